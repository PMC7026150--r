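sex,n,mean,sd,note
male,54,14.5,2.69,n inferred from ANOVA df (2;150) with sibling n=30 and control n=69
female,20,6.81,2.56,n inferred from ANOVA df (2;102) with sibling n=25 and control n=60
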