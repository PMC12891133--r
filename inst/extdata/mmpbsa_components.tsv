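ligand	dE_vdw	dE_vdw_sd	dE_ele	dE_ele_sd	dG_solv	dG_solv_sd
Ganolucidic Acid E	-32.50	2.11	-17.80	1.75	32.50	2.40
Tetracosanoic acid	-13.60	3.10	-3.05	2.10	10.10	2.95
Linolenic acid	-28.50	2.30	-18.50	3.20	15.50	3.60
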