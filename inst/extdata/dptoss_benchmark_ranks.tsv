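# DP-TOSS benchmark: rank of the true topology per protein under six
# edge-scoring schemes; NA = not within the top 100 topologies.
# beta: 1 if the protein contains beta-sheet; experimental: 1 for the ten
# experimental volumes (rows 16-25), 0 for the simulated ones.
no	id	beta	experimental	sses_s	sses_v	sk	sk+g	sk+g+e	sk+e	g	g+e
1	1FLP	0	0	7	6	1	1	1	1	4	17
2	1NG6	0	0	9	7	2	2	1	1	7	15
3	2XB5	0	0	13	10	11	2	9	47	91	NA
4	1BZ4	0	0	5	5	1	1	3	56	87	NA
5	3ACW	0	0	17	15	32	7	24	28	73	61
6	1A7D	0	0	6	4	12	2	17	19	46	94
7	3ODS	0	0	21	16	7	1	34	61	NA	NA
8	3HJL	0	0	20	20	1	1	1	1	4	16
9	1ICX	1	0	13	11	31	12	45	NA	NA	NA
10	1OZ9	1	0	13	12	2	2	3	4	72	NA
11	4OXW	1	0	8	7	6	1	2	2	18	77
12	1YD0	1	0	8	7	31	5	22	NA	NA	65
13	2Y4Z	1	0	8	8	NA	14	59	92	NA	83
14	4YOK	1	0	17	15	NA	37	NA	87	NA	NA
15	4R9A	1	0	14	10	NA	27	NA	NA	NA	NA
16	3FIN	1	1	7	7	1	2	2	5	5	24
17	4CHV	1	1	23	19	NA	NA	NA	NA	NA	NA
18	5I1M	0	1	19	12	NA	NA	NA	NA	NA	NA
19	6F36	0	1	13	7	2	1	3	19	2	63
20	6EM3	1	1	8	8	27	13	77	NA	51	NA
21	4UE4	0	1	6	5	1	1	3	14	11	56
22	5UZB	1	1	13	7	20	9	29	77	NA	NA
23	3C91	1	1	19	19	NA	51	87	NA	NA	NA
24	5O8O	1	1	24	22	NA	NA	NA	NA	NA	NA
25	5M50	1	1	9	8	41	31	55	82	NA	NA
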