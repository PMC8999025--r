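# Marital status and education of the 54-worker three-shift cohort
# (counts per shift group; group1 = morning n=17, group2 = afternoon n=18,
# group3 = night n=19).
section	category	total	group1	group2	group3
marital_status	Married	48	16	17	15
marital_status	Unmarried	6	1	1	4
education	Bachelor's degree	4	1	2	1
education	College	12	5	3	4
education	High school	27	5	11	11
education	Junior high school	1	1	0	0
education	Technical secondary school	10	5	2	3
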