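genotype,n_total,n_selfed,n_crossed
GEN1,28,12,16
GEN2,4,3,1
GEN3,19,19,0
GEN4,33,9,24
GEN5,33,29,4
GEN6,1,1,0
GEN7,33,13,20
GEN8,19,10,9
GEN9,3,2,1
GEN10,14,14,0
GEN11,31,28,3
GEN12,27,6,21
GEN13,33,1,32
GEN14,16,15,1
GEN15,3,2,1
GEN16,31,13,18
GEN17,1,1,0
GEN18,3,0,3
GEN19,30,27,3
GEN20,29,8,21
GEN21,3,3,0
GEN22,20,8,12
GEN23,17,17,0
GEN24,1,1,0
GEN25,32,32,0
GEN26,29,26,3
GEN27,17,15,2
GEN28,13,11,2
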