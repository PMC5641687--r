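item,trait,wave,sex,loading,prop_yes_printed,n_yes,n_no
e1,extraversion,t1,male,0.417,0.306,279,634
e2,extraversion,t1,male,0.428,0.340,294,571
e3,extraversion,t1,male,0.626,0.305,255,580
e4,extraversion,t1,male,0.689,0.172,151,727
e5,extraversion,t1,male,0.286,0.318,299,641
e6,extraversion,t1,male,0.239,0.321,287,608
n1,neuroticism,t1,male,0.676,0.547,538,446
n2,neuroticism,t1,male,0.520,0.456,452,539
n3,neuroticism,t1,male,0.518,0.712,694,281
n4,neuroticism,t1,male,0.571,0.494,476,487
n5,neuroticism,t1,male,0.808,0.627,608,361
n6,neuroticism,t1,male,0.879,0.649,628,340
e1,extraversion,t2,male,0.514,0.200,207,826
e2,extraversion,t2,male,0.527,0.405,403,591
e3,extraversion,t2,male,0.724,0.265,266,736
e4,extraversion,t2,male,0.779,0.232,233,770
e5,extraversion,t2,male,0.363,0.445,461,574
e6,extraversion,t2,male,0.306,0.318,313,672
n1,neuroticism,t2,male,0.720,0.506,528,515
n2,neuroticism,t2,male,0.568,0.521,546,501
n3,neuroticism,t2,male,0.566,0.584,609,433
n4,neuroticism,t2,male,0.619,0.410,424,610
n5,neuroticism,t2,male,0.841,0.596,613,415
n6,neuroticism,t2,male,0.902,0.637,664,378
e1,extraversion,t1,female,0.392,0.437,405,522
e2,extraversion,t1,female,0.520,0.291,266,647
e3,extraversion,t1,female,0.660,0.451,385,468
e4,extraversion,t1,female,0.742,0.218,193,692
e5,extraversion,t1,female,0.296,0.332,329,663
e6,extraversion,t1,female,0.284,0.358,335,602
n1,neuroticism,t1,female,0.620,0.224,234,809
n2,neuroticism,t1,female,0.571,0.355,365,664
n3,neuroticism,t1,female,0.576,0.637,649,370
n4,neuroticism,t1,female,0.549,0.340,344,668
n5,neuroticism,t1,female,0.859,0.504,502,494
n6,neuroticism,t1,female,0.885,0.427,430,576
e1,extraversion,t2,female,0.447,0.322,346,728
e2,extraversion,t2,female,0.581,0.397,421,640
e3,extraversion,t2,female,0.717,0.443,462,580
e4,extraversion,t2,female,0.792,0.256,261,759
e5,extraversion,t2,female,0.341,0.411,442,634
e6,extraversion,t2,female,0.328,0.342,351,676
n1,neuroticism,t2,female,0.656,0.205,226,876
n2,neuroticism,t2,female,0.608,0.361,397,704
n3,neuroticism,t2,female,0.613,0.572,625,468
n4,neuroticism,t2,female,0.586,0.269,293,795
n5,neuroticism,t2,female,0.879,0.538,586,504
n6,neuroticism,t2,female,0.902,0.481,526,568
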