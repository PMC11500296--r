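4
NH3, r(NH) = 1.012 A, HNH = 106.7 deg
N      0.0000000000     0.0000000000     0.0000000000
H      0.9375295737     0.0000000000    -0.3810279498
H     -0.4687647868     0.8119244276    -0.3810279498
H     -0.4687647868    -0.8119244276    -0.3810279498
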