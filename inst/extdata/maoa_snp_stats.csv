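snp,position,alleles,sex,loading,maf,n,hwe_p,n_geno0,n_geno1,n_geno2
rs3788862,43402308,A/G,male,0.989,0.300,1240,NA,816,344,NA
rs5906957,43432254,A/G,male,0.989,0.240,1244,NA,885,275,NA
rs979606,43486086,G/A,male,0.984,0.300,1240,NA,811,349,NA
rs3788862,43402308,A/G,female,0.968,0.280,1258,0.400,618,462,100
rs5906957,43432254,A/G,female,0.968,0.220,1260,0.870,713,406,61
rs979606,43486086,G/A,female,0.959,0.290,1257,0.130,610,461,109
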