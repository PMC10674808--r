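# Published size distribution of small-RNA sequencing reads mapped with
# 0 or 1 mismatches to the totivirus genomes GcTV2-Gc6 and GcTV4-Gc6 and
# to the host Geotrichum candidum reference assembly (LMA-244_clib,
# GCA_013365045.1).  "ND" entries in the published table are stored as 0.
# Columns: per-length totals, perfect-match counts and one-mismatch
# counts for each target.  The ">30" row pools reads longer than 30 nt.
length	gctv2_total	gctv4_total	host_total	gctv2_perfect	gctv4_perfect	host_perfect	gctv2_1mm	gctv4_1mm	host_1mm
10	56987	75858	579036	1450	545	579020	55537	75313	16
11	15616	26851	439532	522	232	436820	15094	26619	2712
12	7309	4859	980610	99	43	866277	7210	4816	114333
13	12614	2410	1247012	21	8	646920	12593	2402	600092
14	615	695	2423441	5	8	257021	610	687	2166420
15	369	386	2374600	0	5	243264	369	381	2131336
16	47	154	1670491	0	0	262674	47	154	1407817
17	133	43	3120220	0	0	301826	133	43	2818394
18	337	49	1246059	0	0	337262	337	49	908797
19	7	30	2103211	0	0	602221	7	30	1500990
20	10	0	12694084	0	0	1312581	10	0	11381503
21	0	0	1503777	0	0	535043	0	0	968734
22	0	0	1025590	0	0	351560	0	0	674030
23	0	0	1181768	0	0	269011	0	0	912757
24	0	0	1518337	0	0	233035	0	0	1285302
25	0	0	240986	0	0	121743	0	0	119243
26	0	0	151291	0	0	79791	0	0	71500
27	0	0	109991	0	0	64998	0	0	44993
28	0	0	87651	0	0	51255	0	0	36396
29	0	0	49420	0	0	23245	0	0	26175
30	0	0	39603	0	0	19653	0	0	19950
>30	0	0	77785	0	0	35462	0	0	42323
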