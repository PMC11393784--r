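exposure	mediator	outcome	beta0	b0_lo	b0_hi	beta1	b1_lo	b1_hi	beta2	b2_lo	b2_hi	ind	ind_lo	ind_hi	prop	prop_lo	prop_hi
age_at_menarche	body_mass_index	NAFLD	-0.188	-0.289	-0.087	-0.130	-0.190	-0.070	0.514	0.403	0.626	-0.067	-0.103	-0.035	35.64	18.62	54.79
age_at_first_sex	body_mass_index	NAFLD	-0.425	-0.658	-0.192	-0.345	-0.429	-0.260	0.514	0.403	0.626	-0.177	-0.239	-0.123	41.65	28.94	56.24
age_at_first_sex	major_depression	NAFLD	-0.425	-0.658	-0.192	-0.304	-0.417	-0.191	0.200	0.025	0.374	-0.061	-0.124	-0.007	14.35	1.65	29.18
age_at_first_sex	educational_attainment	NAFLD	-0.425	-0.658	-0.192	0.384	0.294	0.475	-0.419	-0.770	-0.067	-0.161	-0.309	-0.025	37.88	5.88	72.71
age_at_first_sex	household_income	NAFLD	-0.425	-0.658	-0.192	0.248	0.187	0.310	-0.320	-0.607	-0.033	-0.079	-0.158	-0.008	18.59	1.88	37.18
age_at_first_birth	body_mass_index	NAFLD	-0.154	-0.222	-0.086	-0.109	-0.135	-0.085	0.514	0.403	0.626	-0.056	-0.075	-0.040	36.36	25.97	48.70
age_at_first_birth	major_depression	NAFLD	-0.154	-0.222	-0.086	-0.121	-0.153	-0.089	0.200	0.025	0.374	-0.024	-0.048	-0.003	15.58	1.95	31.17
age_at_first_birth	educational_attainment	NAFLD	-0.154	-0.222	-0.086	0.153	0.129	0.178	-0.419	-0.770	-0.067	-0.064	-0.120	-0.010	41.56	6.49	77.92
age_at_first_birth	household_income	NAFLD	-0.154	-0.222	-0.086	0.109	0.091	0.127	-0.320	-0.607	-0.033	-0.035	-0.068	-0.004	22.73	2.60	44.16
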