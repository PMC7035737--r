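#cross	line	parent_name	trait	mean	sd	n
T485xH8	P1	T485	plant_height	90.78	0.25	15
T485xH8	P2	H8	plant_height	137.28	3.60	15
T485xH8	F1	T485xH8	plant_height	132.28	2.49	15
T485xH8	P1	T485	panicles_per_plant	4.78	0.54	15
T485xH8	P2	H8	panicles_per_plant	3.11	0.42	15
T485xH8	F1	T485xH8	panicles_per_plant	3.77	0.31	15
T485xH8	P1	T485	panicle_length	25.28	0.87	15
T485xH8	P2	H8	panicle_length	28.65	0.26	15
T485xH8	F1	T485xH8	panicle_length	28.44	1.12	15
T485xH8	P1	T485	filled_grains_per_plant	153.39	40.13	15
T485xH8	P2	H8	filled_grains_per_plant	308.72	29.09	15
T485xH8	F1	T485xH8	filled_grains_per_plant	505.33	56.11	15
T485xH8	P1	T485	grain_yield_per_plant	5.14	1.16	15
T485xH8	P2	H8	grain_yield_per_plant	10.89	0.75	15
T485xH8	F1	T485xH8	grain_yield_per_plant	18.72	1.94	15
T485xH8	P1	T485	thousand_grain_weight	34.68	2.98	15
T485xH8	P2	H8	thousand_grain_weight	35.35	1.15	15
T485xH8	F1	T485xH8	thousand_grain_weight	37.21	0.71	15
T485xH8	P1	T485	seed_setting	33.35	4.53	15
T485xH8	P2	H8	seed_setting	55.82	6.19	15
T485xH8	F1	T485xH8	seed_setting	75.16	2.25	15
H1xH8	P1	H1	plant_height	101.39	1.63	15
H1xH8	P2	H8	plant_height	137.28	3.60	15
H1xH8	F1	H1xH8	plant_height	144.53	1.11	15
H1xH8	P1	H1	panicles_per_plant	5.45	0.98	15
H1xH8	P2	H8	panicles_per_plant	3.11	0.42	15
H1xH8	F1	H1xH8	panicles_per_plant	4.67	0.40	15
H1xH8	P1	H1	panicle_length	20.72	0.55	15
H1xH8	P2	H8	panicle_length	28.65	0.26	15
H1xH8	F1	H1xH8	panicle_length	28.44	1.13	15
H1xH8	P1	H1	filled_grains_per_plant	252.73	63.35	15
H1xH8	P2	H8	filled_grains_per_plant	308.72	29.09	15
H1xH8	F1	H1xH8	filled_grains_per_plant	589.10	42.79	15
H1xH8	P1	H1	grain_yield_per_plant	8.88	2.13	15
H1xH8	P2	H8	grain_yield_per_plant	10.89	0.75	15
H1xH8	F1	H1xH8	grain_yield_per_plant	23.18	1.50	15
H1xH8	P1	H1	thousand_grain_weight	35.51	0.22	15
H1xH8	P2	H8	thousand_grain_weight	35.35	1.15	15
H1xH8	F1	H1xH8	thousand_grain_weight	39.55	0.62	15
H1xH8	P1	H1	seed_setting	65.30	3.65	15
H1xH8	P2	H8	seed_setting	55.82	6.19	15
H1xH8	F1	H1xH8	seed_setting	77.04	3.80	15
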