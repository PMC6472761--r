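order	model	progeny	DM	SW	SY	AGI
1	FSTME	521	156.92	20.66	23.70	31.39
2	FSTME	267	148.06	20.36	26.51	31.13
3	FSTME	550	157.05	20.34	22.93	31.02
4	FSTME	556	152.91	19.98	22.83	30.44
5	FSTME	235	152.08	19.13	25.31	30.38
6	FSTME	545	149.86	20.16	23.07	30.36
7	FSTME	537	151.66	20.20	22.17	30.33
8	FSTME	554	151.38	20.32	21.83	30.31
9	FSTME	520	153.18	19.77	22.49	30.24
10	FSTME	262	154.56	18.17	26.44	30.20
11	FSTME	56	154.15	19.80	21.79	30.18
12	FSTME	562	158.58	19.12	21.98	30.14
13	FSTME	568	157.47	19.60	20.81	30.10
14	FSTME	272	154.70	19.24	22.65	30.06
15	FSTME	515	149.72	20.63	20.35	30.04
16	FSTME	266	147.93	19.03	25.45	30.01
17	FSTME	567	158.44	19.63	19.86	29.98
18	FSTME	215	151.38	19.07	23.96	29.97
19	FSTME	546	145.02	20.03	22.67	29.80
20	FSTME	571	154.15	19.50	20.77	29.76
21	FSTME	269	156.09	18.58	22.69	29.75
22	FSTME	569	158.02	18.97	20.90	29.75
23	FSTME	514	151.80	19.49	21.60	29.75
24	FSTME	531	151.52	19.69	20.96	29.71
25	FSTME	239	153.60	18.69	23.08	29.70
26	FSTME	51	158.16	18.83	20.61	29.61
27	FSTME	212	150.14	18.09	25.59	29.60
28	FSTME	516	150.42	19.58	21.20	29.60
29	FSTME	524	153.04	19.07	21.70	29.59
30	FSTME	544	152.91	19.54	20.36	29.59
1	FMTME	521	158.31	20.54	25.49	29.79
2	FMTME	550	157.50	20.22	25.15	29.47
3	FMTME	267	155.95	20.22	25.06	29.33
4	FMTME	556	153.87	19.90	24.09	28.80
5	FMTME	235	157.97	19.00	25.25	28.72
6	FMTME	537	151.56	20.14	23.46	28.67
7	FMTME	545	151.65	20.08	23.55	28.66
8	FMTME	562	157.65	19.03	24.86	28.66
9	FMTME	554	150.68	20.27	23.21	28.65
10	FMTME	262	162.68	17.99	26.43	28.63
11	FMTME	520	153.64	19.69	23.96	28.63
12	FMTME	56	153.21	19.74	23.79	28.60
13	FMTME	568	154.41	19.55	23.98	28.59
14	FMTME	567	153.70	19.61	23.72	28.54
15	FMTME	272	155.49	19.16	24.37	28.49
16	FMTME	515	146.55	20.62	22.04	28.36
17	FMTME	215	155.10	18.97	24.35	28.33
18	FMTME	569	155.41	18.91	24.13	28.28
19	FMTME	266	154.80	18.91	24.39	28.28
20	FMTME	269	157.11	18.49	24.68	28.23
21	FMTME	571	151.64	19.46	23.22	28.20
22	FMTME	51	155.26	18.80	24.05	28.19
23	FMTME	239	155.65	18.60	24.34	28.13
24	FMTME	514	151.12	19.44	23.15	28.13
25	FMTME	531	149.66	19.65	22.74	28.09
26	FMTME	546	146.99	19.98	22.25	28.02
27	FMTME	524	152.57	19.01	23.47	28.02
28	FMTME	544	149.87	19.51	22.71	28.01
29	FMTME	512	154.70	18.58	23.97	27.99
30	FMTME	516	149.23	19.54	22.62	27.96
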