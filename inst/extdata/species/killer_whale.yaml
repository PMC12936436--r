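G: 0.00094
R: 0.048
M: 0.00001
xs: 11
zeta: 0.051
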