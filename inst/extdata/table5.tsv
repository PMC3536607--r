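trait	breed	h2_dgv	h2_dgv_se	r_g	r_g_se
Birth weight	Limousin	1.00	0.00	0.58	0.04
Calving ease direct	Limousin	1.00	0.00	0.52	0.05
Calving ease maternal	Limousin	1.00	0.00	0.51	0.03
Carcass weight	Limousin	1.00	0.00	0.56	0.06
Docility	Limousin	1.00	0.00	0.40	0.04
Marbling	Limousin	1.00	0.00	0.65	0.06
Rib eye muscle area	Limousin	1.00	0.00	0.63	0.05
Scrotal circumference	Limousin	1.00	0.00	0.45	0.05
Stayability	Limousin	1.00	0.00	0.39	0.06
Weaning weight direct	Limousin	1.00	0.00	0.58	0.04
Weaning weight maternal	Limousin	1.00	0.00	0.46	0.07
Yield grade	Limousin	1.00	0.00	0.67	0.05
Yearling weight	Limousin	1.00	0.00	0.76	0.08
Birth weight	Simmental	1.00	0.00	0.65	0.03
Calving ease direct	Simmental	1.00	0.00	0.45	0.02
Calving ease maternal	Simmental	0.99	0.02	0.32	0.02
Carcass weight	Simmental	1.00	0.00	0.59	0.04
Fat thickness	Simmental	0.98	0.02	0.29	0.02
Marbling	Simmental	1.00	0.00	0.63	0.04
Rib eye muscle area	Simmental	1.00	0.00	0.59	0.04
Shear force	Simmental	1.00	0.00	0.53	0.08
Stayability	Simmental	1.00	0.00	0.58	0.06
Weaning weight direct	Simmental	1.00	0.00	0.52	0.04
Weaning weight maternal	Simmental	1.00	0.00	0.34	0.03
Yield grade	Simmental	1.00	0.00	0.62	0.06
Yearling weight	Simmental	1.00	0.00	0.45	0.02
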