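# PCR marker patterns of nine P. fluorescens complex model strains
# and four out-of-complex negative controls
sample_id	DGPf_0	DGPf_1	DGPf_2	DGPf_3	DGPf_4	DGPf_5	DGPf_6	DGPf_7	DGPf_8	expected_group
P. fluorescens F113	+	+	-	-	-	-	-	-	-	P. corrugata
P. fluorescens Q2-87	+	+	-	-	-	-	-	-	-	P. corrugata
P. fluorescens Q8r1-96	+	+	-	-	-	-	-	-	-	P. corrugata
P. brassicacearum NFM421	+	+	-	-	-	-	-	-	-	P. corrugata
P. chlororaphis PCL1319	-	-	+	-	-	-	-	-	+	P. chlororaphis
P. chlororaphis PCL1606	-	-	+	-	-	-	-	-	+	P. chlororaphis
P. protegens Pf-5	-	-	+	-	+	-	+	-	-	P. protegens
P. fluorescens Pf0-1	+	-	+	-	-	-	-	-	-	P. koreensis
P. fluorescens SBW25	-	-	-	-	-	+	-	+	-	P. fluorescens
P. putida KT2440	-	-	+	-	-	-	-	-	-	none
P. syringae pv. tomato DC3000	-	-	-	-	-	-	-	-	-	none
P. aeruginosa PAO1	-	-	-	-	-	-	-	-	-	none
E. coli DH5alpha	-	-	-	-	-	-	-	-	-	none
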