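# MSC-specific kinetic parameters estimated by curve fitting against the
# mouse flow-cytometry biodistribution experiment (fixture "table1").
# partition: unitless; rate constants: 1/h. The blood row carries only a
# depletion rate constant (circulating pools have no arrest/release).
organ,partition,k_arrest,k_release,k_depletion
blood,NA,NA,NA,0.636
lung,742.733,5.434,0.108,0.0589
liver,262.699,1.395,0.066,0.060
spleen,1633.24,0.608,0.856,0.002
kidney,305.351,1.727,0.054,0.151
heart,3.097,1.251,0.016,0.039
rest_of_body,6.765,0.143,0.957,0.148
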