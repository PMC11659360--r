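region_id	region_name	listed_double	total_double
HPF	Hippocampal formation	4860	5561
CTXsp	Cortical subplate	1082	1747
STR	Striatum	800	1523
PAL	Pallidum	441	1366
HY	Hypothalamus	5712	8474
MB	Midbrain	7535	10959
P	Pons	2387	4712
MY	Medulla	3236	5245
Other	Other	0	1129
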