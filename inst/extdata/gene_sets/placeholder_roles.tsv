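gene	role	protein_length	domains
APC	tsg	2843	
MLH1	tsg	756	
MSH2	tsg	934	
MSH6	tsg	1360	
PMS2	tsg	862	
MUTYH	tsg	549	
POLE	tsg	2286	
POLD1	tsg	1107	
SMAD4	tsg	552	
BMPR1A	tsg	532	
STK11	tsg	433	
PTEN	tsg	403	
TP53	tsg	393	
KRAS	oncogene	189	
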