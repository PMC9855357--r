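"name","source","record","start","end"
"GluN2A_CTD","synthetic_ctd_sequences.fasta",1,838,1464
"GluN2B_CTD","synthetic_ctd_sequences.fasta",2,838,1482
"CTD1A","synthetic_ctd_sequences.fasta",1,873,1211
"CTD1B","synthetic_ctd_sequences.fasta",2,874,1212
"CTD2A","synthetic_ctd_sequences.fasta",1,1243,1464
"CTD2B","synthetic_ctd_sequences.fasta",2,1250,1482
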