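trait	mean_WW	se_WW	mean_WL	se_WL
GFP	36.01	0.16	30.09	0.14
GY	18.33	0.11	7.63	0.14
TDM	59.93	0.31	42.17	0.26
MAT	136.8	0.16	132.3	0.16
GN	300.3	2.2	207.8	2.73
HI	31.6	0.19	22.18	0.39
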