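G: 0.003
R: 0.208
M: 0.05
xs: 5
zeta: 0.182
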