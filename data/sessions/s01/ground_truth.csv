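"trial","approach_init","arrival","drink_time","approach","drink"
1,1.43754007917077,1.89816225301474,NA,TRUE,FALSE
2,1.48618904341085,1.96666666666667,4,TRUE,TRUE
3,1.39630188184685,1.86666666666667,4,TRUE,TRUE
4,1.36053422242242,1.80328718734285,NA,TRUE,FALSE
5,1.27570525909107,1.7223909119765,NA,TRUE,FALSE
6,1.27405391516766,1.73068069328244,NA,TRUE,FALSE
7,1.37154105541646,1.83585285479205,NA,TRUE,FALSE
8,1.27356451422713,1.73333333333335,4,TRUE,TRUE
9,NA,NA,NA,FALSE,FALSE
10,1.45090685438691,1.93333333333334,4,TRUE,TRUE
11,NA,NA,NA,FALSE,FALSE
12,1.38355286205501,1.82446876193086,NA,TRUE,FALSE
13,NA,NA,NA,FALSE,FALSE
14,NA,NA,NA,FALSE,FALSE
15,1.2789939297287,1.72739831774186,NA,TRUE,FALSE
16,1.52111821031406,1.9666666666667,4,TRUE,TRUE
17,NA,NA,NA,FALSE,FALSE
18,1.41251678930905,1.86666666666667,4,TRUE,TRUE
19,1.38553567310191,1.86666666666667,4,TRUE,TRUE
20,1.22223324577203,1.69094444541258,NA,TRUE,FALSE
21,1.143350573617,1.60000000000002,4,TRUE,TRUE
22,NA,NA,NA,FALSE,FALSE
23,1.17411559522031,1.62473442610349,NA,TRUE,FALSE
24,1.28436750395599,1.74387143937247,NA,TRUE,FALSE
25,1.29414320109356,1.76666666666665,4,TRUE,TRUE
26,NA,NA,NA,FALSE,FALSE
27,1.42842507945181,1.88392536990966,NA,TRUE,FALSE
28,1.3743527335713,1.83333333333337,4,TRUE,TRUE
29,NA,NA,NA,FALSE,FALSE
30,1.43940819889622,1.89999999999998,4,TRUE,TRUE
31,1.25500131928288,1.71837275493885,NA,TRUE,FALSE
32,1.23169529593338,1.70000000000005,4,TRUE,TRUE
33,1.3173790644762,1.76666666666665,4,TRUE,TRUE
34,1.31889611488577,1.78761855795346,NA,TRUE,FALSE
35,1.53186125612251,2,4,TRUE,TRUE
36,1.33530566572699,1.79999999999995,4,TRUE,TRUE
37,1.49490218075061,1.9666666666667,4,TRUE,TRUE
38,1.51370336719265,1.9666666666667,4,TRUE,FALSE
39,1.40500613824724,1.85280771271005,NA,TRUE,FALSE
40,NA,NA,NA,FALSE,FALSE
41,1.29366489227777,1.76666666666665,4,TRUE,TRUE
42,1.26786552553904,1.73333333333335,4,TRUE,TRUE
43,1.35690125291444,1.79999999999995,4,TRUE,TRUE
44,1.3216453921325,1.79999999999995,NA,TRUE,FALSE
45,1.4074492066095,1.87290035805972,NA,TRUE,FALSE
46,1.26513108797735,1.73202784651266,NA,TRUE,FALSE
47,NA,NA,NA,FALSE,FALSE
48,NA,NA,NA,FALSE,FALSE
49,NA,NA,NA,FALSE,FALSE
50,NA,NA,NA,FALSE,FALSE
51,1.45387473805886,1.89999999999986,4,TRUE,TRUE
52,NA,NA,NA,FALSE,FALSE
53,NA,NA,NA,FALSE,FALSE
54,NA,NA,NA,FALSE,FALSE
55,NA,NA,NA,FALSE,FALSE
56,NA,NA,NA,FALSE,FALSE
57,NA,NA,NA,FALSE,FALSE
58,NA,NA,NA,FALSE,FALSE
59,NA,NA,NA,FALSE,FALSE
60,NA,NA,NA,FALSE,FALSE
61,NA,NA,NA,FALSE,FALSE
62,NA,NA,NA,FALSE,FALSE
63,NA,NA,NA,FALSE,FALSE
64,NA,NA,NA,FALSE,FALSE
65,1.44503859985707,1.8991699556509,NA,TRUE,FALSE
66,NA,NA,NA,FALSE,FALSE
67,NA,NA,NA,FALSE,FALSE
68,NA,NA,NA,FALSE,FALSE
69,NA,NA,NA,FALSE,FALSE
70,NA,NA,NA,FALSE,FALSE
71,1.46377439850994,1.9325210504544,NA,TRUE,FALSE
72,NA,NA,NA,FALSE,FALSE
73,1.15498841248245,1.60953927983837,NA,TRUE,FALSE
74,1.38313143591495,1.86666666666679,4,TRUE,TRUE
75,NA,NA,NA,FALSE,FALSE
76,NA,NA,NA,FALSE,FALSE
77,NA,NA,NA,FALSE,FALSE
78,NA,NA,NA,FALSE,FALSE
79,1.43301474667169,1.90000000000009,4,TRUE,TRUE
80,1.26813373822824,1.73154585960629,NA,TRUE,FALSE
81,1.53695266510749,2,4,TRUE,TRUE
82,NA,NA,NA,FALSE,FALSE
83,NA,NA,NA,FALSE,FALSE
84,1.3520461547273,1.83333333333348,4,TRUE,TRUE
85,NA,NA,NA,FALSE,FALSE
86,NA,NA,NA,FALSE,FALSE
87,NA,NA,NA,FALSE,FALSE
88,NA,NA,NA,FALSE,FALSE
89,NA,NA,NA,FALSE,FALSE
90,NA,NA,NA,FALSE,FALSE
91,NA,NA,NA,FALSE,FALSE
92,NA,NA,NA,FALSE,FALSE
93,NA,NA,NA,FALSE,FALSE
94,NA,NA,NA,FALSE,FALSE
95,NA,NA,NA,FALSE,FALSE
96,NA,NA,NA,FALSE,FALSE
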