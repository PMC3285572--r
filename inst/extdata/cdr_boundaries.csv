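scheme,chain,region,start,end
kabat,light,L1,24,34
kabat,light,L2,50,56
kabat,light,L3,89,97
kabat,heavy,H1,31,35B
kabat,heavy,H2,50,65
kabat,heavy,H3,95,102
chothia,light,L1,24,34
chothia,light,L2,50,56
chothia,light,L3,89,97
chothia,heavy,H1,26,32
chothia,heavy,H2,52,56
chothia,heavy,H3,95,102
imgt,light,L1,27,38
imgt,light,L2,56,65
imgt,light,L3,105,117
imgt,heavy,H1,27,38
imgt,heavy,H2,56,65
imgt,heavy,H3,105,117
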