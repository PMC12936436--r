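G: 0.0025
R: 0.325
M: 0.0522
xs: 2
zeta: 0.2
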