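variable	group	mean	sd	n
age_years	CW	24.39	3.49	26
age_years	AN	23.23	5.26	26
age_years	BN	24.64	4.22	25
body_mass_index	CW	21.61	1.21	26
body_mass_index	AN	16.23	1.09	26
body_mass_index	BN	23.56	5.89	25
novelty_seeking	CW	18.42	5.27	26
novelty_seeking	AN	13.89	6.02	26
novelty_seeking	BN	22.20	6.70	25
harm_avoidance	CW	10.08	4.74	26
harm_avoidance	AN	23.65	5.94	26
harm_avoidance	BN	22.48	5.93	25
reward_dependence	CW	16.54	3.47	26
reward_dependence	AN	15.04	3.04	26
reward_dependence	BN	15.60	4.57	25
depression_bdi	CW	1.27	1.28	26
depression_bdi	AN	21.27	12.94	26
depression_bdi	BN	22.68	14.58	25
drive_for_thinness	CW	2.42	3.51	26
drive_for_thinness	AN	19.96	5.98	26
drive_for_thinness	BN	21.92	4.65	25
bulimia_edi3	CW	0.92	1.23	26
bulimia_edi3	AN	3.89	4.97	26
bulimia_edi3	BN	20.00	5.43	25
body_dissatisfaction	CW	4.62	4.26	26
body_dissatisfaction	AN	24.31	8.99	26
body_dissatisfaction	BN	30.44	7.58	25
sensitivity_to_reward	CW	5.00	2.95	26
sensitivity_to_reward	AN	6.69	3.71	26
sensitivity_to_reward	BN	7.56	3.38	25
sensitivity_to_punishment	CW	4.42	2.69	26
sensitivity_to_punishment	AN	12.96	3.85	26
sensitivity_to_punishment	BN	12.56	3.80	25
state_anxiety	CW	26.46	4.82	26
state_anxiety	AN	55.23	11.95	26
state_anxiety	BN	50.52	13.14	25
trait_anxiety	CW	28.04	4.29	26
trait_anxiety	AN	56.39	11.98	26
trait_anxiety	BN	58.80	9.75	25
sucrose_pleasantness	CW	4.92	2.43	26
sucrose_pleasantness	AN	4.58	2.32	26
sucrose_pleasantness	BN	5.88	2.57	25
sucrose_sweetness	CW	8.23	0.82	26
sucrose_sweetness	AN	8.31	1.19	26
sucrose_sweetness	BN	8.28	0.98	25
education_years	CW	16.52	1.92	26
education_years	AN	14.39	2.25	26
education_years	BN	15.77	3.09	25
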