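# PCR marker patterns of nineteen field isolates from rhizosphere,
# endosphere and soil
sample_id	DGPf_0	DGPf_1	DGPf_2	DGPf_3	DGPf_4	DGPf_5	DGPf_6	DGPf_7	DGPf_8	expected_group
EMC3	+	-	+	-	-	-	-	-	-	P. koreensis
EMC5	+	-	+	-	-	-	-	-	-	P. koreensis
RMT7	+	-	+	-	-	-	-	-	-	P. koreensis
RMC4	+	-	+	-	-	-	-	-	-	P. koreensis
RMC9	+	-	+	-	-	-	-	-	-	P. koreensis
3.2	+	-	+	-	-	-	-	-	-	P. koreensis
EMC11	+	-	+	+	-	-	-	-	-	P. jessenii
RMT1	+	-	+	+	-	-	-	-	-	P. jessenii
RMT2	+	-	+	+	-	-	-	-	-	P. jessenii
RMC8	+	-	+	+	-	-	-	-	-	P. jessenii
HFL1	+	-	+	+	-	-	-	-	-	P. jessenii
HFL4	+	-	+	+	-	-	-	-	-	P. jessenii
EMC7	-	-	-	-	-	+	-	+	-	P. fluorescens
EMT2	-	-	-	-	-	+	-	+	-	P. fluorescens
EMT8	-	-	-	-	-	+	-	+	-	P. fluorescens
RMT4	-	-	-	-	-	+	-	+	-	P. fluorescens
RMT12	-	-	-	-	-	+	-	+	-	P. fluorescens
RMP9	+	+	-	-	-	-	-	-	-	P. corrugata
7.3	+	+	-	-	-	-	-	-	-	P. corrugata
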