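BLOCK: offset: B000001 len: 4 phased: 4
1	1	0	chr10	595
2	1	0	chr10	1462
3	0	1	chr10	1902
4	0	1	chr10	2487
********
BLOCK: offset: B000002 len: 3 phased: 3
5	0	1	chr10	3227
6	0	1	chr10	3414
7	1	0	chr10	9561
********
BLOCK: offset: B000003 len: 2 phased: 2
8	0	1	chr10	11254
9	0	1	chr10	11618
********
BLOCK: offset: B000004 len: 5 phased: 5
10	0	1	chr10	11879
11	1	0	chr10	13078
12	0	1	chr10	15889
13	1	0	chr10	19201
14	0	1	chr10	21242
********
BLOCK: offset: B000005 len: 3 phased: 3
15	1	0	chr10	22095
16	1	0	chr10	22479
17	0	1	chr10	24268
********
BLOCK: offset: B000006 len: 2 phased: 2
18	0	1	chr10	25132
19	1	0	chr10	27781
********
BLOCK: offset: B000007 len: 2 phased: 2
20	1	0	chr10	29477
21	1	0	chr10	29818
********
BLOCK: offset: B000008 len: 1 phased: 1
22	1	0	chr10	30615
********
BLOCK: offset: B000009 len: 2 phased: 2
23	0	1	chr10	31073
24	0	1	chr10	31194
********
BLOCK: offset: B000010 len: 4 phased: 4
25	1	0	chr10	31244
26	0	1	chr10	33110
27	1	0	chr10	33339
28	0	1	chr10	34567
********
BLOCK: offset: B000011 len: 3 phased: 3
29	1	0	chr10	36123
30	1	0	chr10	36175
31	1	0	chr10	36418
********
BLOCK: offset: B000012 len: 5 phased: 5
32	1	0	chr10	36901
33	1	0	chr10	40045
34	0	1	chr10	40204
35	1	0	chr10	41884
36	1	0	chr10	43223
********
BLOCK: offset: B000013 len: 2 phased: 2
37	1	0	chr10	45525
38	1	0	chr10	48275
********
BLOCK: offset: B000014 len: 3 phased: 3
39	1	0	chr10	49432
40	1	0	chr10	50315
41	0	1	chr10	54217
********
BLOCK: offset: B000015 len: 2 phased: 2
42	0	1	chr10	56304
43	1	0	chr10	56722
********
BLOCK: offset: B000016 len: 2 phased: 2
44	0	1	chr10	58618
45	1	0	chr10	59144
********
BLOCK: offset: B000017 len: 2 phased: 2
46	0	1	chr10	59784
47	1	0	chr10	61019
********
BLOCK: offset: B000018 len: 1 phased: 1
48	1	0	chr10	61800
********
BLOCK: offset: B000019 len: 1 phased: 1
49	0	1	chr10	63143
********
BLOCK: offset: B000020 len: 2 phased: 2
50	1	0	chr10	63966
51	1	0	chr10	64659
********
BLOCK: offset: B000021 len: 3 phased: 3
52	1	0	chr10	65051
53	0	1	chr10	66451
54	1	0	chr10	67538
********
BLOCK: offset: B000022 len: 3 phased: 3
55	0	1	chr10	69840
56	1	0	chr10	72691
57	0	1	chr10	73084
********
BLOCK: offset: B000023 len: 3 phased: 3
58	0	1	chr10	75558
59	0	1	chr10	77282
60	0	1	chr10	77643
********
BLOCK: offset: B000024 len: 5 phased: 5
61	1	0	chr10	79776
62	0	1	chr10	81763
63	1	0	chr10	82273
64	0	1	chr10	82614
65	0	1	chr10	82697
********
BLOCK: offset: B000025 len: 3 phased: 3
66	0	1	chr10	83107
67	0	1	chr10	83257
68	1	0	chr10	83972
********
BLOCK: offset: B000026 len: 2 phased: 2
69	0	1	chr10	85012
70	1	0	chr10	85195
********
BLOCK: offset: B000027 len: 2 phased: 2
71	0	1	chr10	87812
72	1	0	chr10	88177
********
BLOCK: offset: B000028 len: 4 phased: 4
73	0	1	chr10	88736
74	0	1	chr10	88934
75	0	1	chr10	89214
76	1	0	chr10	89276
********
BLOCK: offset: B000029 len: 2 phased: 2
77	0	1	chr10	89387
78	0	1	chr10	90396
********
BLOCK: offset: B000030 len: 1 phased: 1
79	0	1	chr10	92373
********
BLOCK: offset: B000031 len: 4 phased: 4
80	1	0	chr10	92979
81	0	1	chr10	92994
82	0	1	chr10	93582
83	0	1	chr10	94293
********
BLOCK: offset: B000032 len: 2 phased: 2
84	1	0	chr10	94668
85	1	0	chr10	94890
********
BLOCK: offset: B000033 len: 3 phased: 3
86	1	0	chr10	95248
87	0	1	chr10	95270
88	1	0	chr10	95641
********
BLOCK: offset: B000034 len: 4 phased: 4
89	1	0	chr10	98541
90	1	0	chr10	100003
91	0	1	chr10	100115
92	1	0	chr10	101296
********
BLOCK: offset: B000035 len: 1 phased: 1
93	1	0	chr10	102963
********
BLOCK: offset: B000036 len: 1 phased: 1
94	1	0	chr10	103844
********
BLOCK: offset: B000037 len: 2 phased: 2
95	1	0	chr10	104112
96	0	1	chr10	104497
********
BLOCK: offset: B000038 len: 4 phased: 4
97	1	0	chr10	104824
98	0	1	chr10	106361
99	0	1	chr10	106541
100	1	0	chr10	107271
********
BLOCK: offset: B000039 len: 4 phased: 4
101	0	1	chr10	108449
102	1	0	chr10	109024
103	1	0	chr10	109468
104	1	0	chr10	110478
********
BLOCK: offset: B000040 len: 6 phased: 6
105	1	0	chr10	113820
106	1	0	chr10	114582
107	1	0	chr10	116261
108	1	0	chr10	116793
109	0	1	chr10	116871
110	0	1	chr10	118046
********
BLOCK: offset: B000041 len: 3 phased: 3
111	1	0	chr10	118129
112	1	0	chr10	118392
113	1	0	chr10	119518
********
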