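variable	gbm_a	astro_a	gbm_b	astro_b	printed_p
sex_male_vs_female	61	37	50	41	0.308
age_ge50_vs_lt50	86	32	25	46	0.001
kps_ge80_vs_lt80	85	67	26	11	0.112
volume_lt40_vs_ge40	81	55	30	23	0.711
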