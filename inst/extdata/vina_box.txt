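center_x = 49.137
center_y = 21.547
center_z = 32.93
size_x = 44.25
size_y = 47.25
size_z = 43.5
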