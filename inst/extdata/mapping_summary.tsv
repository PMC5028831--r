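sample	group	all_reads	unmapped	mapped	mapped_rate	unique_mapped	unique_rate	repeat_mapped	junction_all	junction_unique
A1	QHMM	18752596	1415576	17337020	0.925	16437180	0.877	899853	7829834	7826739
A2	QHMM	17482106	1531813	15950293	0.912	14905935	0.853	1044371	6856974	6854001
A3	QHMM	16488130	1302393	15185737	0.921	14372858	0.872	812891	6700137	6697036
B1	STH	17458226	1334282	16123944	0.924	15292633	0.876	831323	6846232	6843592
B2	STH	14790361	1156221	13634140	0.922	12779250	0.864	854906	5638984	5636750
B3	STH	17408297	1371310	16036987	0.921	15237071	0.875	799930	7226780	7223760
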