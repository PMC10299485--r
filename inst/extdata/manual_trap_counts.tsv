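trap	sd	ot
1	28	2
2	22	12
3	6	1
4	14	4
5	36	1
6	25	16
7	131	4
8	50	0
9	196	4
10	23	3
11	57	3
12	9	0
13	68	4
14	74	1
15	32	23
16	13	4
17	14	6
18	36	22
19	5	20
20	17	3
21	22	8
22	165	0
23	16	1
24	1	0
25	58	2
26	16	2
27	36	14
28	28	16
29	15	18
30	11	2
31	6	6
32	4	2
33	23	13
34	24	13
35	26	7
36	18	5
37	20	8
38	41	16
39	1	1
40	7	2
41	12	2
42	10	1
43	7	5
44	8	0
45	115	2
46	24	1
47	10	0
48	25	0
49	89	15
50	12	2
51	1	0
52	111	0
53	3	0
54	43	2
55	12	0
56	56	1
57	34	1
58	131	0
59	5	2
60	12	1
61	53	1
62	6	0
63	125	0
64	2	0
65	70	2
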