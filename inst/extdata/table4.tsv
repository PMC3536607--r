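trait	breed	var_trait	var_dgv	cov
Birth weight	Limousin	2.80	0.93	0.93
Calving ease direct	Limousin	55.92	11.46	13.12
Calving ease maternal	Limousin	78.12	25.91	22.97
Carcass weight	Limousin	107.82	25.67	29.67
Docility	Limousin	423.76	84.86	75.85
Marbling	Limousin	0.009	0.002	0.003
Rib eye muscle area	Limousin	5.00	1.53	1.73
Scrotal circumference	Limousin	831.28	154.71	162.65
Stayability	Limousin	93.07	11.91	12.96
Weaning weight direct	Limousin	68.08	18.76	20.80
Weaning weight maternal	Limousin	26.00	2.83	3.94
Yield grade	Limousin	0.018	0.005	0.006
Yearling weight	Limousin	111.76	22.82	38.44
Birth weight	Simmental	3.49	1.29	1.39
Calving ease direct	Simmental	108.62	29.90	25.72
Calving ease maternal	Simmental	118.60	28.24	18.50
Carcass weight	Simmental	122.07	30.87	36.49
Fat thickness	Simmental	7.10	1.29	0.64
Marbling	Simmental	0.145	0.051	0.054
Rib eye muscle area	Simmental	12.82	4.16	4.33
Shear force	Simmental	0.085	0.021	0.022
Stayability	Simmental	114.30	28.00	32.90
Weaning weight direct	Simmental	75.14	18.01	19.13
Weaning weight maternal	Simmental	53.37	10.14	7.86
Yield grade	Simmental	0.073	0.026	0.027
Yearling weight	Simmental	726.42	61.77	96.28
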