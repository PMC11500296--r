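! STO-3G minimal basis, standard published exponents/coefficients.
! Each primitive set follows from the universal 3-Gaussian expansion of a
! Slater orbital scaled by the standard zeta values (a rule the test suite
! cross-checks).
element H
S 3
    3.42525091   0.15432897
    0.62391373   0.53532814
    0.16885540   0.44463454
end
element C
S 3
   71.61683700   0.15432897
   13.04509600   0.53532814
    3.53051220   0.44463454
SP 3
    2.94124940  -0.09996723   0.15591627
    0.68348310   0.39951283   0.60768372
    0.22228990   0.70011547   0.39195739
end
element N
S 3
   99.10616900   0.15432897
   18.05231200   0.53532814
    4.88566020   0.44463454
SP 3
    3.78045590  -0.09996723   0.15591627
    0.87849664   0.39951283   0.60768372
    0.28571437   0.70011547   0.39195739
end
element O
S 3
  130.70932000   0.15432897
   23.80886100   0.53532814
    6.44360830   0.44463454
SP 3
    5.03315130  -0.09996723   0.15591627
    1.16959610   0.39951283   0.60768372
    0.38038900   0.70011547   0.39195739
end
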