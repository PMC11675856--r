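gene	type	strand	start	end	size_printed	igs_printed	start_codon	stop_codon
D-loop	control_region	H	1	1148	1148	0	NA	NA
tRNA-Phe	tRNA	H	1149	1216	68	-1	NA	NA
12S rRNA	rRNA	H	1216	2181	966	0	NA	NA
tRNA-Val	tRNA	H	2182	2256	75	0	NA	NA
16S rRNA	rRNA	H	2257	3882	1626	-1	NA	NA
tRNA-Leu(UUR)	tRNA	H	3882	3955	74	11	NA	NA
ND1	PCG	H	3967	4941	975	0	ATG	TAA
tRNA-Ile	tRNA	H	4942	5013	72	6	NA	NA
tRNA-Gln	tRNA	L	5020	5090	71	-1	NA	NA
tRNA-Met	tRNA	H	5090	5158	69	0	NA	NA
ND2	PCG	H	5159	6197	1039	0	ATG	T--
tRNA-Trp	tRNA	H	6198	6275	78	2	NA	NA
tRNA-Ala	tRNA	L	6278	6346	69	3	NA	NA
tRNA-Asn	tRNA	L	6350	6422	73	2	NA	NA
tRNA-Cys	tRNA	L	6425	6491	67	0	NA	NA
tRNA-Tyr	tRNA	L	6492	6561	70	1	NA	NA
COI	PCG	H	6563	8113	1551	-9	GTG	AGG
tRNA-Ser(UCN)	tRNA	L	8105	8179	75	2	NA	NA
tRNA-Asp	tRNA	H	8182	8250	69	1	NA	NA
COII	PCG	H	8252	8935	684	1	ATG	TAA
tRNA-Lys	tRNA	H	8937	9004	68	1	NA	NA
ATP8	PCG	H	9006	9170	165	-10	ATG	TAA
ATP6	PCG	H	9161	9844	684	-1	ATG	TAA
COIII	PCG	H	9844	10627	784	0	ATG	T--
tRNA-Gly	tRNA	H	10628	10696	69	0	NA	NA
ND3	PCG	H	10697	11048	352	1	ATG	TAA
tRNA-Arg	tRNA	H	11050	11118	69	0	NA	NA
ND4L	PCG	H	11119	11415	297	-7	ATG	TAA
ND4	PCG	H	11409	12786	1378	0	ATG	T--
tRNA-His	tRNA	H	12787	12855	69	0	NA	NA
tRNA-Ser(AGN)	tRNA	H	12856	12922	69	0	NA	NA
tRNA-Leu(CUN)	tRNA	H	12923	12993	71	0	NA	NA
ND5	PCG	H	12994	14811	1818	4	ATG	TAA
CYTB	PCG	H	14816	15958	1143	1	ATG	TAG
tRNA-Thr	tRNA	H	15960	16028	69	2	NA	NA
tRNA-Pro	tRNA	L	16031	16099	69	6	NA	NA
ND6	PCG	L	16106	16627	522	1	ATG	TAG
tRNA-Glu	tRNA	L	16629	16696	68	0	NA	NA
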