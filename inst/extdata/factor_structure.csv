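sex,var_a,var_b,value
male,E16,E26,0.592
male,E16,N16,-0.220
male,E16,N26,-0.221
male,E26,N16,-0.077
male,E26,N26,-0.169
male,N16,N26,0.526
male,G,E16,-0.164
male,G,E26,0.040
male,G,N16,0.068
male,G,N26,-0.019
female,E16,E26,0.565
female,E16,N16,-0.279
female,E16,N26,-0.248
female,E26,N16,-0.189
female,E26,N26,-0.312
female,N16,N26,0.479
female,G,E16,-0.036
female,G,E26,-0.110
female,G,N16,0.067
female,G,N26,0.077
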