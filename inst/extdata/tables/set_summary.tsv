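set_name	locus	design	str_distance_kb	mean_gc_pct	hits_matched_3prime	success_pct	best_tested_length	ddg_m_mm	sim_best_length	concordance	match_pair	mismatch_pair
P30FG	P30	FG	18	36	no	76	21*	-1.15	21, 22	r	C-G	T-G
P30FG-1	P30	FG-1	18	35	no	82	21	-1.80	21	r	C-G	T-G
P30FA	P30	FA	18	33	no	83	20*	-0.40	21	r	T-A	C-A
P30FA-1	P30	FA-1	18	30	no	95	22	-1.01	22	r	T-A	C-A
P30RC	P30	RC	18	27	no	92	24*	-0.49	24	r	G-C	A-C
P30RC-1	P30	RC-1	18	30	2, 24	70	23	-2.18	23, 27	r	G-C	A-C
P38FA	P38	FA	17	77	no	89	21	-0.60	11	w	T-A	A-G
P38FA-1	P38	FA-1	17	71	no	86	20	-1.04	12	w	T-A	A-G
P38FC	P38	FC	17	83	2, 9, 10, 13+	72	15	-1.19	10	w	G-C	T-C
P38FC-1	P38	FC-1	17	79	7, 10+	49	n.s.	-1.83	12	w	G-C	T-C
P224FC	P224	FC	13	40	no	90	19*	-0.37	18	r	G-C	A-C
P224FT	P224	FT	13	34	no	86	19*, 20*	-0.70	19	r	A-T	G-T
P224RG	P224	RG	13	60	no	93	17	-1.31	14	r	C-G	T-G
P224RA	P224	RA	13	53	no	86	17	-0.48	15, 16	r	T-A	C-A
P240FC	P240	FC	14	37	no	82	22*	-0.48	22	r	G-C	A-C
P240FC-1	P240	FC-1	14	40	no	83	20*	-2.43	20, 21	r	G-C	A-C
P240FT	P240	FT	14	32	no	84	22	-0.60	22	r	A-T	T-C
P240FT-1	P240	FT-1	14	35	no	94	20	-1.52	20, 21	r	A-T	T-C
P240RG	P240	RG	14	42	no	79	18*	-1.14	19	r	C-G	T-G
P240RG-1	P240	RG-1	14	40	no	73	20	-1.21	20	r	C-G	T-G
P240RA	P240	RA	14	39	no	88	18	-0.87	18, 20	r	T-A	C-A
P244FG	P244	FG	35	66	49	73	13*	-0.95	15	r	C-G	T-G
P244FG-1	P244	FG-1	35	65	no	78	15	-2.11	14	r	C-G	T-G
P244FA	P244	FA	35	57	116+	54	n.s.	0.05	no	r	T-A	C-A
P244FA-1	P244	FA-1	35	59	0.6+	76	15	-1.04	15	r	T-A	C-A
P244RC	P244	RC	35	68	20, 29+	68	14*	-0.66	13	r	G-C	A-C
P244RC-1	P244	RC-1	35	71	20+	71	14	-2.16	14	r	G-C	A-C
P244RT	P244	RT	35	60	2, 9, 13+	62	13	-0.69	13	r	A-T	G-T
P244RT-1	P244	RT-1	35	64	9, 13+	66	14	-1.01	14	r	A-T	G-T
TatFT	Tat	FT	15	33	no	84	20	-0.57	20	r	T-A	G-T
TatFC	Tat	FC	15	38	no	87	18	-0.52	20	r	G-C	A-C
TatFG	Tat	FG	15	40	no	75	19	-1.39	20	r	C-G	T-G
TatFG-1	Tat	FG-1	15	43	no	81	18	-2.77	19, 20	r	C-G	T-G
rs13304202FA	rs13304202	FA	37	34	no	77	19	0.42	no	w	T-A	C-A
rs13304202FA-1	rs13304202	FA-1	37	38	no	76	22	-1.55	20, 22	r	T-A	C-A
rs13304202RC	rs13304202	RC	37	39	no	70	21	-1.17	22	r	G-C	A-C
rs13304202RC-1	rs13304202	RC-1	37	43	no	81	21*	-3.00	21, 24	r	G-C	A-C
SeqE2071RG	Seq.E2071	RG	0.3	35	no	78	20	-1.19	19	r	C-G	T-G
SeqE2071RA	Seq.E2071	RA	0.3	30	no	91	20	-0.13	20	r	T-A	C-A
SeqF4204FG	Seq.F4204	FG	0.15	53	0.3 kb with matched 3' end	67	17	-0.71	18	r	C-G	G-G
SeqF4204FC	Seq.F4204	FC	0.15	53	0.3 kb but no matched 3' end	98	17	-0.83	14	r	C-G	C-C
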