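ligand	selective_for	n_modes	delta_ea	first_ea	mean_ea	sd_ea	mean_rmsd_lb	mean_rmsd_ub
Ambrisentan	A	10	1.9	-10.8	-9.0	0.97	1.855	3.895
Methadone	A	10	1.9	-9.9	-8.9	0.60	1.696	4.326
Triamterene	A	10	1.8	-9.6	-8.4	0.45	2.176	4.693
Prednisone	A	10	1.7	-11.0	-8.7	1.20	1.639	4.357
Metaxalone	A	10	1.6	-8.8	-8.0	0.59	2.085	3.697
Doxapram	A	10	1.5	-10.9	-9.2	1.07	1.617	3.620
Ergotamine	B	10	12.6	-12.0	-11.5	0.31	2.568	8.325
Ciclesonide	B	10	9.9	-11.8	-11.0	0.49	2.789	5.359
Suvorexant	B	10	7.0	-10.1	-9.1	0.30	4.740	8.674
Nintedanib	B	10	6.8	-10.6	-10.2	0.24	2.664	6.214
Lurasidone	B	10	6.0	-11.1	-11.1	0.55	2.985	5.905
Amcinonide	B	10	5.0	-10.9	-10.2	0.40	3.320	6.541
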