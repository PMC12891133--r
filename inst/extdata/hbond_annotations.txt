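Ganolucidic Acid E: SER66, THR68
Tetracosanoic acid: THR56, ARG109
Linolenic acid: ASP79
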