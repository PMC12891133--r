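ligand	vina_energy
Ganolucidic Acid E	-6.0
Tetracosanoic acid	-5.8
Linolenic acid	-6.5
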