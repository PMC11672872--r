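transcript_id	gene_symbol	chrom	strand	exon_starts	exon_ends	cds_start_tx	cds_end_tx
NM_001037955	Dusp22	ctg_Dusp22	+	101,1001	800,1900	101	1300
NM_134068	Dusp22	ctg_Dusp22	+	101,1001,2001	800,1300,2150	101	1060
NM_001164037	Ly6e	ctg_Ly6e	+	101,501,1601	200,1400,2200	302	1300
NM_001164038	Ly6e	ctg_Ly6e	+	101,551,1601	200,1400,2200	252	1250
NM_001164040	Ly6e	ctg_Ly6e	+	101,601,1601	200,1400,2200	202	1200
NM_001171053	Mta3	ctg_Mta3	+	101,1001,2001	800,1800,2235	101	1642
NM_001171052	Mta3	ctg_Mta3	+	101,1001,2001,3001	800,1800,2120,4057	101	1857
NM_177466	Rab11fip5	ctg_Rab11fip5	+	101,1001,2001	800,1600,2900	101	1600
NM_001003955	Rab11fip5	ctg_Rab11fip5	+	101,1001,1701,2001	800,1600,1790,2900	101	1690
NM_001166623	Rbmx	ctg_Rbmx	+	101,501,1801	250,1600,2400	201	1700
NM_011252	Rbmx	ctg_Rbmx	+	101,504,1801	250,1600,2400	198	1697
NM_001163757	Skor	ctg_Skor	+	101,1101	900,2000	101	1300
NM_001163758	Skor	ctg_Skor	+	191,1101	900,2000	131	1210
NM_001079694	Srsf5	ctg_Srsf5	+	101,501,1901	250,1700,2350	251	1348
NM_009159	Srsf5	ctg_Srsf5	+	101,505,1901	250,1700,2350	247	1344
NM_001042708	Ilf3	ctg_Ilf3	+	101,1001,1801	800,1600,3000	101	1600
NM_001042707	Ilf3	ctg_Ilf3	+	101,1001,3201	800,1600,3950	101	1750
NM_027557	Pwwp2a	ctg_Pwwp2a	+	101,1001	800,1800	101	1300
NM_001164231	Pwwp2a	ctg_Pwwp2a	+	101,1001,2001	800,1350,2600	101	1150
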