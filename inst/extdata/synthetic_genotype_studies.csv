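"study_id","gene","variant","case_ref","case_het","case_hom","control_ref","control_het","control_hom"
"sim01","SIMGENE","simvar",76,62,33,108,70,13
"sim02","SIMGENE","simvar",71,75,26,217,169,34
"sim03","SIMGENE","simvar",146,110,83,178,163,31
"sim04","GENE2","var2",243,169,61,98,89,22
"sim05","GENE2","var2",177,173,38,118,119,17
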