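# Distributional islands of Great Basin kangaroo mice: log10 area (km2),
# sample size n, observed number of unique composite haplotypes h.
island_id	species	log10_area_km2	n	h
western_clade	M_megacephalus	4.846	65	23
idaho_isolate	M_megacephalus	2.585	2	1
main_central_unit	M_megacephalus	4.937	61	31
mono_isolate	M_megacephalus	3.449	8	8
eastern_clade	M_megacephalus	4.300	50	25
main_western_unit	M_pallidus	4.397	44	19
deep_springs_isolate	M_pallidus	2.837	10	1
main_eastern_unit	M_pallidus	4.125	41	21
alamo_isolate	M_pallidus	3.090	3	1
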