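ligand	selective_for	n_modes	delta_ea	first_ea	mean_ea	sd_ea	mean_rmsd_lb	mean_rmsd_ub
Afzelchin	A	6	2.1	-10.2	-8.3	0.95	1.937	6.013
Aminoclonazepam	A	6	1.9	-10.7	-9.3	0.78	2.708	4.454
Dihydroisorhamnetin	A	6	1.7	-10.2	-9.0	0.68	1.254	5.850
Bisphenol A	A	6	1.5	-9.3	-8.7	0.42	1.989	5.145
N-cinnamoyloctopamin	A	6	1.3	-10.4	-10.0	0.24	2.816	4.520
Azukisapogenol	B	6	15.0	-10.5	-10.1	0.23	1.926	2.790
D-maslinic acid	B	6	11.0	-10.6	-10.2	0.25	1.687	4.801
Isoliensinine	B	6	7.4	-11.3	-10.9	0.26	2.491	6.986
Dukunolide D	B	6	4.8	-11.0	-10.8	0.13	2.211	5.002
Zanthobisquinolone	B	6	3.2	-11.1	-10.7	0.23	1.770	5.954
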