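snp	chr	pos	gene	location	gwas_p	eqtl_p	pfp	fc	histone	probe	meth_p
rs4648881	1	25197155	MTFR1L	5prime	5e-07	4.0e-03	2.33e-02	-1.30	none		
rs9633402	1	247946160	TRIM58	5prime	3e-06	5.4e-04	1.15e-02	1.21	none	cg12689806	8.45e-02
rs79893749	3	46253650	CCR3	intron	2e-07	2.5e-04	1.68e-02	-1.27	H3K4me1_Enh	cg04111761	7.78e-03
rs4869313	5	96223880	ELL2	5prime	9e-08	2.4e-02	4.04e-02	-1.26	none		
rs41291794	6	32425762	HLA-DPA1	3prime	4e-15	1.4e-02	8.20e-04	1.33	none	cg13906813	1.64e-02
rs7069750	10	90762376	ACTA2	5prime	3e-08	4.9e-20	3.60e-03	1.27	none	cg03111039	6.52e-08
rs7069750	10	90762376	ANKRD22	5prime	3e-08	4.0e-03	3.64e-02	1.21	none	cg15103050	1.52e-01
rs12598357	16	28340945	SH2B1	5prime	4e-09	4.4e-06	3.83e-04	1.68	none	cg07884168	1.55e-02
rs12598357	16	28340945	SULT1A1	3prime	4e-09	9.6e-07	5.51e-03	-1.31	none	cg09685060	1.41e-09
rs12928404	16	28847246	SH2B1	5prime	6e-07	1.9e-04	3.83e-04	1.68	none	cg06932837	5.13e-05
rs12928404	16	28847246	SULT1A1	5prime	6e-07	5.0e-06	5.51e-03	-1.31	none	cg26603685	1.72e-07
rs2847293	18	12782448	MPPE1	5prime	1e-12	3.9e-02	2.01e-02	-1.36	none	cg14599440	2.01e-03
rs149850873	18	12885120	CEP192	5prime	5e-07	6.0e-03	4.90e-03	-1.37	H3K4me1_Enh,H3K4me3_Pro	cg00686761	1.78e-01
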