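"trial","approach_init","arrival","drink_time","approach","drink"
1,1.62010086414192,2.06666666666666,4,TRUE,TRUE
2,1.66665728872239,2.1181199436076,NA,TRUE,FALSE
3,1.62715775322714,2.10326189715415,NA,TRUE,FALSE
4,NA,NA,NA,FALSE,FALSE
5,1.6836397197273,2.13371924938014,NA,TRUE,FALSE
6,1.67994039035831,2.13200896034638,NA,TRUE,FALSE
7,1.74599533322005,2.2,4,TRUE,TRUE
8,1.75779027127965,2.23333333333333,4,TRUE,TRUE
9,1.73245517535952,2.19783512866124,NA,TRUE,FALSE
10,1.71681108032035,2.16666666666666,4,TRUE,TRUE
11,1.61159980092503,2.06666666666666,4,TRUE,TRUE
12,1.58020958479335,2.0307810531308,NA,TRUE,FALSE
13,NA,NA,NA,FALSE,FALSE
14,1.6711909893321,2.13333333333333,4,TRUE,TRUE
15,1.60438571501015,2.06818004266052,NA,TRUE,FALSE
16,1.74891010396993,2.20000000000005,4,TRUE,TRUE
17,1.91069219760516,2.38029040082665,NA,TRUE,FALSE
18,1.7007427131781,2.16666666666663,4,TRUE,TRUE
19,1.6836701353202,2.15312236708894,NA,TRUE,FALSE
20,NA,NA,NA,FALSE,FALSE
21,1.74219551293049,2.20000000000005,4,TRUE,TRUE
22,1.79165782350765,2.27055298894027,NA,TRUE,FALSE
23,1.85768359814119,2.33333333333337,4,TRUE,TRUE
24,1.70976690663235,2.18909489267196,NA,TRUE,FALSE
25,1.78767874484618,2.26399138085549,NA,TRUE,FALSE
26,1.58243733094571,2.0333333333333,4,TRUE,TRUE
27,1.78367904698894,2.26589308505254,NA,TRUE,FALSE
28,1.78072697043149,2.23333333333335,4,TRUE,TRUE
29,NA,NA,NA,FALSE,FALSE
30,1.72848905695491,2.19999999999993,4,TRUE,TRUE
31,1.55915692549638,2.02702814278507,NA,TRUE,FALSE
32,1.77281961136327,2.23333333333335,4,TRUE,TRUE
33,1.74582529644442,2.19999999999993,4,TRUE,TRUE
34,1.68659988519903,2.16666666666674,4,TRUE,TRUE
35,1.71020337229606,2.16978581746412,NA,TRUE,FALSE
36,1.53913379008759,1.99408448391273,NA,TRUE,FALSE
37,1.62061860128165,2.06666666666661,4,TRUE,TRUE
38,1.64816510915898,2.09999999999991,4,TRUE,TRUE
39,1.76246678518419,2.23443206250658,NA,TRUE,FALSE
40,NA,NA,NA,FALSE,FALSE
41,1.59058632242909,2.04000106214858,NA,TRUE,FALSE
42,1.74440742183788,2.20000000000005,4,TRUE,TRUE
43,1.76836694929511,2.23333333333335,4,TRUE,TRUE
44,1.62529395012962,2.09999999999991,4,TRUE,TRUE
45,1.6675436643925,2.12058971611168,NA,TRUE,FALSE
46,1.59808829635381,2.06666666666661,4,TRUE,TRUE
47,NA,NA,NA,FALSE,FALSE
48,NA,NA,NA,FALSE,FALSE
49,NA,NA,NA,FALSE,FALSE
50,NA,NA,NA,FALSE,FALSE
51,NA,NA,NA,FALSE,FALSE
52,NA,NA,NA,FALSE,FALSE
53,NA,NA,NA,FALSE,FALSE
54,NA,NA,NA,FALSE,FALSE
55,NA,NA,NA,FALSE,FALSE
56,1.7014133236155,2.16666666666674,4,TRUE,TRUE
57,NA,NA,NA,FALSE,FALSE
58,NA,NA,NA,FALSE,FALSE
59,NA,NA,NA,FALSE,FALSE
60,1.73363884630453,2.1854210444726,NA,TRUE,FALSE
61,NA,NA,NA,FALSE,FALSE
62,1.62687693624275,2.09416259564478,NA,TRUE,FALSE
63,NA,NA,NA,FALSE,FALSE
64,NA,NA,NA,FALSE,FALSE
65,NA,NA,NA,FALSE,FALSE
66,1.69423749654925,2.16666666666652,NA,TRUE,FALSE
67,NA,NA,NA,FALSE,FALSE
68,NA,NA,NA,FALSE,FALSE
69,NA,NA,NA,FALSE,FALSE
70,NA,NA,NA,FALSE,FALSE
71,NA,NA,NA,FALSE,FALSE
72,NA,NA,NA,FALSE,FALSE
73,NA,NA,NA,FALSE,FALSE
74,NA,NA,NA,FALSE,FALSE
75,NA,NA,NA,FALSE,FALSE
76,NA,NA,NA,FALSE,FALSE
77,NA,NA,NA,FALSE,FALSE
78,NA,NA,NA,FALSE,FALSE
79,NA,NA,NA,FALSE,FALSE
80,NA,NA,NA,FALSE,FALSE
81,NA,NA,NA,FALSE,FALSE
82,1.73789071982674,2.19999999999982,4,TRUE,TRUE
83,NA,NA,NA,FALSE,FALSE
84,NA,NA,NA,FALSE,FALSE
85,1.71548150304216,2.16807826686045,NA,TRUE,FALSE
86,NA,NA,NA,FALSE,FALSE
87,NA,NA,NA,FALSE,FALSE
88,1.71333380592569,2.16401970436164,NA,TRUE,FALSE
89,NA,NA,NA,FALSE,FALSE
90,NA,NA,NA,FALSE,FALSE
91,NA,NA,NA,FALSE,FALSE
92,NA,NA,NA,FALSE,FALSE
93,NA,NA,NA,FALSE,FALSE
94,NA,NA,NA,FALSE,FALSE
95,NA,NA,NA,FALSE,FALSE
96,NA,NA,NA,FALSE,FALSE
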