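group	total	n_female	n_male	printed_female_pct	printed_male_pct
helpseek	19182	11828	7354	61.7	38.3
selfrep	4691	2879	1812	61.4	38.6
antidep	4222	2602	1620	61.6	38.4
smith	3166	1963	1203	62.0	38.0
icd10	1605	990	615	61.7	38.3
cidisf	3571	2200	1371	61.6	38.4
k1	10977	6487	4490	59.1	40.9
k2	5233	3307	1926	63.2	36.8
k3	2574	1691	883	65.7	34.3
k4	1275	859	416	67.4	32.6
k5	378	270	108	71.4	28.6
k6	47	31	16	66.0	34.0
all_cases	20484	12645	7839	61.7	38.3
controls	25462	11384	14078	44.7	55.3
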