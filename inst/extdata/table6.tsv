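trait	breed	cohort	r2_pa	efficiency
Birth weight	Limousin	genotyped	0.42	0.89
Calving ease direct	Limousin	genotyped	0.41	0.81
Calving ease maternal	Limousin	genotyped	0.41	0.80
Carcass weight	Limousin	genotyped	0.39	0.89
Docility	Limousin	genotyped	0.35	0.68
Marbling	Limousin	genotyped	0.38	1.05
Rib eye muscle area	Limousin	genotyped	0.38	1.02
Scrotal circumference	Limousin	genotyped	0.32	0.80
Stayability	Limousin	genotyped	0.32	0.69
Weaning weight direct	Limousin	genotyped	0.40	0.92
Weaning weight maternal	Limousin	genotyped	0.39	0.74
Yield grade	Limousin	genotyped	0.38	1.08
Yearling weight	Limousin	genotyped	0.36	1.28
Birth weight	Simmental	genotyped	0.37	1.06
Calving ease direct	Simmental	genotyped	0.36	0.75
Calving ease maternal	Simmental	genotyped	0.34	0.55
Carcass weight	Simmental	genotyped	0.31	1.07
Fat thickness	Simmental	genotyped	0.33	0.51
Marbling	Simmental	genotyped	0.33	1.10
Rib eye muscle area	Simmental	genotyped	0.32	1.05
Shear force	Simmental	genotyped	0.14	1.44
Stayability	Simmental	genotyped	0.17	1.39
Weaning weight direct	Simmental	genotyped	0.35	0.87
Weaning weight maternal	Simmental	genotyped	0.35	0.57
Yield grade	Simmental	genotyped	0.28	1.17
Yearling weight	Simmental	genotyped	0.36	0.75
Birth weight	Simmental	young	0.37	1.08
Calving ease direct	Simmental	young	0.33	0.78
Calving ease maternal	Simmental	young	0.28	0.60
Carcass weight	Simmental	young	0.28	1.11
Fat thickness	Simmental	young	0.22	0.62
Marbling	Simmental	young	0.20	1.41
Rib eye muscle area	Simmental	young	0.19	1.35
Shear force	Simmental	young	0.07	2.04
Stayability	Simmental	young	0.15	1.48
Weaning weight direct	Simmental	young	0.33	0.91
Weaning weight maternal	Simmental	young	0.28	0.64
Yield grade	Simmental	young	0.20	1.40
Yearling weight	Simmental	young	0.32	0.79
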