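"study_id","arm","n","mean","sd","median","min","max"
"geno1","TT",60,16.95,5.88,NA,NA,NA
"geno1","CC",200,12.39,5.83,NA,NA,NA
"geno2","TT",60,17.44,6.44,NA,NA,NA
"geno2","CC",200,12.56,5.81,NA,NA,NA
"geno3","TT",60,16.16,6.07,NA,NA,NA
"geno3","CC",200,11.94,6.17,NA,NA,NA
"geno4","TT",60,17.25,6.35,NA,NA,NA
"geno4","CC",200,10.99,5.83,NA,NA,NA
"geno5","TT",45,NA,NA,20.2,6,31.8
"geno5","CC",120,11.8,5.6,NA,NA,NA
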