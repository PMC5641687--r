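snp_a,snp_b,sex,r
rs3788862,rs5906957,male,0.680
rs3788862,rs979606,male,0.750
rs5906957,rs979606,male,0.520
rs3788862,rs5906957,female,0.700
rs3788862,rs979606,female,0.790
rs5906957,rs979606,female,0.560
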