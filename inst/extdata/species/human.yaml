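G: 0.00041
R: 0.071
M: 0.00001
xs: 13
zeta: 0.036
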