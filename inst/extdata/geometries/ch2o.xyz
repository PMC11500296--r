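4
formaldehyde, r(CO) = 1.208 A, r(CH) = 1.116 A, HCH = 116.5 deg
C      0.0000000000     0.0000000000     0.0000000000
O      0.0000000000     0.0000000000     1.2080000000
H      0.9489930831     0.0000000000    -0.5872547388
H     -0.9489930831     0.0000000000    -0.5872547388
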