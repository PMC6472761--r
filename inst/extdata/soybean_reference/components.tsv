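model	trait	sigma_g2	sigma_int2	sigma_e2	sigma_phen2	h2_prog	c2_int	cv_g	cv_e	ac_prog
FSTME	DM	128.625	33.9228	56.5253	219.073	0.8298	0.1548	0.0791	0.0524	0.9087
FSTME	SW	1.8045	0.6244	1.5008	3.9297	0.7624	0.1589	0.0729	0.0665	0.8691
FSTME	SY	8.6171	10.0727	36.4566	55.1464	0.4368	0.1827	0.1410	0.2901	0.6557
FMTME	DM	130.947	31.6741	56.5234	219.144	0.8383	0.1445	0.0798	0.0524	0.9485
FMTME	SW	1.8084	0.6228	1.5006	3.9318	0.7631	0.1584	0.0730	0.0665	0.8713
FMTME	SY	10.4882	8.2995	36.4419	55.2297	0.5064	0.1503	0.1555	0.2899	0.9330
BSTME	DM	129.598	34.2204	56.7499	220.569	NA	0.1552	0.0794	0.0525	0.9633
BSTME	SW	1.8158	0.6278	1.5081	3.9518	NA	0.1588	0.0732	0.0666	0.6337
BSTME	SY	8.3801	10.2834	36.6665	55.3299	NA	0.1859	0.1390	0.2908	0.7367
BMTME	DM	131.616	31.2917	57.1089	220.017	NA	0.1422	0.0801	0.0527	0.9733
BMTME	SW	1.8161	0.6253	1.5152	3.9566	NA	0.1580	0.0732	0.0668	0.6355
BMTME	SY	11.0459	6.9344	37.5989	55.5792	NA	0.1248	0.1596	0.2945	0.8941
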