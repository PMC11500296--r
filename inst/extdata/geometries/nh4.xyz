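5
ammonium cation (+1), tetrahedral, r(NH) = 1.021 A
N      0.0000000000     0.0000000000     0.0000000000
H      0.5894746248     0.5894746248     0.5894746248
H      0.5894746248    -0.5894746248    -0.5894746248
H     -0.5894746248     0.5894746248    -0.5894746248
H     -0.5894746248    -0.5894746248     0.5894746248
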