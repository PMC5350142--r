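# Pooled (metagenomic) marker patterns of three environmental samples;
# expected_groups = compatible phylogroup set
sample_id	DGPf_0	DGPf_1	DGPf_2	DGPf_3	DGPf_4	DGPf_5	DGPf_6	DGPf_7	DGPf_8	expected_groups
Soil sample	+	-	-	+	-	+	-	+	-	P. mandelii;P. fluorescens
Rhizosphere sample 1	+	+	+	+	-	+	-	+	-	P. corrugata;P. koreensis;P. jessenii;P. mandelii;P. fluorescens
Rhizosphere sample 2	+	-	+	+	-	+	-	+	+	P. koreensis;P. jessenii;P. mandelii;P. fluorescens;P. chlororaphis
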