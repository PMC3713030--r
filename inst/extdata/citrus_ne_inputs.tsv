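locus	group	theta	theta_lower	theta_upper	n	ne_published	ne_published_lower	ne_published_upper
HYB	Citron	0.00314	NA	NA	6	11867	6767	20799
HYB	Mandarin	0.00240	NA	NA	18	9068	4643	15672
HYB	Pummelo	0.00287	NA	NA	8	10855	5728	18778
HYB	Trifoliate	0.00192	NA	NA	5	7262	3506	14569
HYB	MRCA_all	0.00122	NA	NA	NA	4609	824	13307
HYB	MRCA_PCM	0.0014	NA	NA	NA	5271	1243	15147
HYB	MRCA_CM	0.00108	NA	NA	NA	4077	707	12298
LGT	Citron	0.00133	NA	NA	8	3938	1705	9077
LGT	Mandarin	0.00317	NA	NA	17	9360	5222	15721
LGT	Pummelo	0.00203	NA	NA	7	5980	2537	12015
LGT	Trifoliate	0.00069	NA	NA	2	2024	469	6384
LGT	MRCA_all	0.0011	NA	NA	NA	3236	628	8626
LGT	MRCA_PCM	0.00111	NA	NA	NA	3269	628	8301
LGT	MRCA_CM	0.00069	NA	NA	NA	2047	316	7230
MDH	Citron	0.00311	NA	NA	7	20210	11137	34773
MDH	Mandarin	0.00330	NA	NA	22	21384	12182	35377
MDH	Pummelo	0.00102	NA	NA	5	6587	1642	16244
MDH	Trifoliate	0.00076	NA	NA	4	4913	1116	14927
MDH	MRCA_all	0.00092	NA	NA	NA	5945	610	17841
MDH	MRCA_PCM	0.00076	NA	NA	NA	4913	201	16556
MDH	MRCA_CM	0.00095	NA	NA	NA	6146	980	17069
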