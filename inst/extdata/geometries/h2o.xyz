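3
H2O, r(OH) = 0.9572 A, HOH = 104.52 deg
O      0.0000000000     0.0000000000     0.0000000000
H      0.7569503273     0.0000000000     0.5858822766
H     -0.7569503273     0.0000000000     0.5858822766
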