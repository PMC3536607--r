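trait	h2	n_limousin	rel_limousin	n_simmental	rel_simmental
Birth weight	0.42	2185	0.65	2664	0.59
Calving ease direct	0.12	1687	0.61	2443	0.57
Calving ease maternal	0.13	1669	0.59	2441	0.43
Carcass weight	0.40	1459	0.67	2663	0.46
Docility	0.35	1225	0.54		
Fat thickness	0.35			2463	0.59
Marbling	0.54	1447	0.61	2439	0.57
Rib eye muscle area	0.46	1449	0.62	2435	0.55
Scrotal circumference	0.43	1294	0.44		
Shear force	0.40			1045	0.36
Stayability	0.21	757	0.50	563	0.66
Weaning weight direct	0.30	2150	0.53	2663	0.55
Weaning weight maternal	0.14	1480	0.55	2661	0.41
Yield grade	0.40	1446	0.62	2574	0.45
Yearling weight	0.29	1780	0.43	2663	0.56
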