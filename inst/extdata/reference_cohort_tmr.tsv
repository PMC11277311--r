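sample	total_mutations	per_mb	log10_per_mb
1_P	15227	362.55	2.56
1_R	25619	609.99	2.79
2_P	11898	283.29	2.45
2_R	16759	399.02	2.60
3_P	6281	149.55	2.17
3_R	39456	939.43	2.97
4_P	11858	282.33	2.45
4_R	22414	533.67	2.73
5_P	35395	842.74	2.93
5_R	45060	1072.86	3.03
6_P	9111	216.93	2.34
6_R	20473	487.45	2.69
7_P	20877	497.07	2.70
7_R	10648	253.52	2.40
8_P	17404	414.38	2.62
8_R	22285	530.60	2.72
9_P	6119	145.69	2.16
9_R	7341	174.79	2.24
10_P	11005	262.02	2.42
10_R	29776	708.95	2.85
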