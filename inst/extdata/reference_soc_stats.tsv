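soc	n	ror	ror_lo	ror_hi	prr	prr_lo	prr_hi	chi2	ebgm	ebgm05
gastrointestinal disorders	97	5.3	4.15	6.77	3.84	3.28	4.49	223.12	3.84	3.12
hepatobiliary disorders	9	3.39	1.75	6.59	3.32	1.74	6.34	14.7	3.32	2.10
immune system disorders	7	2.14	1.21	4.53	2.11	1.22	4.36	4.15	2.11	1.13
metabolism and nutrition disorders	8	1.28	0.64	2.59	1.28	0.64	2.54	0.49	1.28	0.71
psychiatric disorders	19	1.16	0.73	1.84	1.15	0.75	1.77	0.37	1.15	0.78
infections and infestations	15	0.92	0.55	1.54	0.92	0.56	1.5	0.11	0.92	0.6
musculoskeletal and connective tissue disorders	14	0.85	0.5	1.45	0.86	0.52	1.43	0.36	0.86	0.55
general disorders and administration site conditions	40	0.73	0.52	1.02	0.77	0.57	1.03	3.35	0.77	0.58
nervous system disorders	18	0.7	0.44	1.13	0.72	0.46	1.13	2.14	0.72	0.48
renal and urinary disorders	4	0.67	0.25	1.8	0.68	0.26	1.81	0.63	0.68	0.3
vascular disorders	4	0.61	0.23	1.65	0.62	0.23	1.65	0.96	0.62	0.27
respiratory thoracic and mediastinal disorders	9	0.61	0.32	1.19	0.62	0.32	1.18	2.15	0.62	0.36
investigations	11	0.6	0.33	1.1	0.62	0.34	1.12	2.76	0.62	0.37
injury poisoning and procedural complications	17	0.6	0.37	0.98	0.62	0.39	0.99	4.31	0.62	0.41
skin and subcutaneous tissue disorders	6	0.36	0.16	0.82	0.38	0.17	0.83	6.52	0.38	0.19
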