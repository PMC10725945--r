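roi_label	tract_name	overlap_voxels	structure_voxels	printed_fraction
GBM_KPS	corticospinal_left	827	27876	0.02
GBM_KPS	inferior_longitudinal_fasciculus_left	299	13859	0.02
GBM_KPS	inferior_occipito_frontal_fasciculus_left	313	11032	0.02
GBM_KPS	fornix_left	504	10145	0.04
GBM_KPS	internal_capsule_left	608	10078	0.06
GBM_KPS	cortico_ponto_cerebellum_left	271	6672	0.04
GBM_KPS	optic_radiations_left	1288	4419	0.29
GBM_KPS	arcuate_anterior_segment_left	1402	4095	0.34
GBM_KPS	long_segment_left	916	2984	0.30
GBM_OS	inferior_occipito_frontal_fasciculus_left	610	11032	0.05
GBM_OS	fornix_left	287	10145	0.02
GBM_OS	uncinate_left	496	7310	0.06
GBM_OS	anterior_commissure_left	120	4875	0.02
ASTRO_KPS	corpus_callosum_left	1794	46399	0.03
ASTRO_KPS	fornix_left	212	10145	0.02
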