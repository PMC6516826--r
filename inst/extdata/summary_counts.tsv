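label	numerator	denominator	digits
vip_sustained_firing	214	237	1
vip_adapting_firing	20	237	1
vip_transient_firing	3	237	1
vip_stellate_icc	39	42	0
vip_laminar_spread_gt100um	35	42	0
vip_orientation_within_15deg	7	42	0
vip_spiny_dendrites	81	86	0
nt_sustained_firing	32	55	1
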