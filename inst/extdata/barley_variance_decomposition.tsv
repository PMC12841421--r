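trait	var_G	prop_G	p_value_G	var_ENV	prop_ENV	p_value_ENV	var_resid	prop_resid
GFP	6.41	17.59	1.6e-35	17.51	48.01	2.1e-259	12.55	34.40
GN	2140.39	19.39	6.0e-30	4254.48	38.53	1.5e-197	4645.76	42.08
GW	0.00	0.82	0.25	0.00	75.48	0	0.00	23.70
GY	5.30	7.37	9.6e-41	57.24	79.63	0	9.35	13.00
HEA	18.13	77.61	7e-289	0.78	3.32	4.6e-52	4.45	19.06
HI	19.00	13.78	2.9e-12	43.54	31.59	2.7e-135	75.29	54.62
MAT	8.99	29.22	2.7e-60	10.14	32.95	1.3e-195	11.64	37.83
TDM	30.89	12.86	2.0e-43	158.72	66.09	0	50.55	21.05
VDW	21.22	28.36	2.1e-33	12.94	12.29	3.0e-81	40.68	59.35
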