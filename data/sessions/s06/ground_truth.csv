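"trial","approach_init","arrival","drink_time","approach","drink"
1,1.65392291894465,2.1,4,TRUE,TRUE
2,1.78744205644614,2.26666666666667,4,TRUE,TRUE
3,1.63417780935211,2.09999999999999,4,TRUE,TRUE
4,1.54752417741219,2.01658844600121,NA,TRUE,FALSE
5,1.59581337301876,2.06666666666666,4,TRUE,TRUE
6,1.81553701373741,2.30000000000001,4,TRUE,TRUE
7,1.60730665462268,2.06644188333303,NA,TRUE,FALSE
8,1.69949323296584,2.1448380157662,NA,TRUE,FALSE
9,1.68354769070993,2.16666666666669,4,TRUE,TRUE
10,1.58326496706974,2.0333333333333,4,TRUE,TRUE
11,1.64191275386827,2.09570040013637,NA,TRUE,FALSE
12,1.75844580084697,2.23333333333335,4,TRUE,TRUE
13,1.66923716625797,2.13333333333333,4,TRUE,TRUE
14,1.59842852736426,2.06666666666661,NA,TRUE,FALSE
15,1.72167199643525,2.17413522933293,NA,TRUE,FALSE
16,NA,NA,NA,FALSE,FALSE
17,1.61350626330875,2.08596662379182,NA,TRUE,FALSE
18,1.74188714940931,2.20000000000005,4,TRUE,TRUE
19,1.78547682945464,2.26666666666665,4,TRUE,TRUE
20,1.68243230132055,2.16666666666663,4,TRUE,TRUE
21,1.66452670171316,2.13495614742862,NA,TRUE,FALSE
22,1.71807730492321,2.19999999999993,4,TRUE,TRUE
23,1.74305300016863,2.22724988429491,NA,TRUE,FALSE
24,1.63782495396993,2.08604031382129,NA,TRUE,FALSE
25,1.83293951249095,2.28690639777733,NA,TRUE,FALSE
26,1.5736889407865,2.0333333333333,4,TRUE,TRUE
27,1.73447905112857,2.20000000000005,NA,TRUE,FALSE
28,1.61443823180434,2.0587270784813,NA,TRUE,FALSE
29,1.76133970135311,2.23674156398829,NA,TRUE,FALSE
30,1.42153223976243,1.90000000000009,4,TRUE,TRUE
31,1.56902073708375,2.02148024238022,NA,TRUE,FALSE
32,NA,NA,NA,FALSE,FALSE
33,1.7197037390099,2.20000000000005,4,TRUE,TRUE
34,1.67448526244266,2.13533273745952,NA,TRUE,FALSE
35,1.81794991531297,2.27513626692826,NA,TRUE,FALSE
36,1.57866019503035,2.0333333333333,4,TRUE,TRUE
37,1.5643767615154,2.04411564599718,NA,TRUE,FALSE
38,1.71315798794285,2.16666666666674,4,TRUE,TRUE
39,1.72855639826707,2.18708991218978,NA,TRUE,FALSE
40,1.7483379589828,2.20000000000005,NA,TRUE,FALSE
41,1.64340523614396,2.1120277777004,NA,TRUE,FALSE
42,1.71553747046369,2.15981857050201,NA,TRUE,FALSE
43,1.74696665238889,2.20000000000005,4,TRUE,TRUE
44,1.65032469762264,2.09999999999991,NA,TRUE,FALSE
45,1.67569213476895,2.13982929609097,NA,TRUE,FALSE
46,1.95006690971331,2.43364314325163,NA,TRUE,FALSE
47,NA,NA,NA,FALSE,FALSE
48,1.68044298562359,2.13333333333321,4,TRUE,TRUE
49,1.82410538037084,2.299442847725,NA,TRUE,FALSE
50,NA,NA,NA,FALSE,FALSE
51,NA,NA,NA,FALSE,FALSE
52,1.65289424385423,2.13174436418331,NA,TRUE,FALSE
53,NA,NA,NA,FALSE,FALSE
54,NA,NA,NA,FALSE,FALSE
55,NA,NA,NA,FALSE,FALSE
56,NA,NA,NA,FALSE,FALSE
57,NA,NA,NA,FALSE,FALSE
58,NA,NA,NA,FALSE,FALSE
59,NA,NA,NA,FALSE,FALSE
60,1.72575601721201,2.20000000000005,4,TRUE,TRUE
61,NA,NA,NA,FALSE,FALSE
62,1.70424038248598,2.16042171608024,NA,TRUE,FALSE
63,NA,NA,NA,FALSE,FALSE
64,NA,NA,NA,FALSE,FALSE
65,1.6871884672255,2.16666666666674,4,TRUE,TRUE
66,NA,NA,NA,FALSE,FALSE
67,NA,NA,NA,FALSE,FALSE
68,NA,NA,NA,FALSE,FALSE
69,NA,NA,NA,FALSE,FALSE
70,1.63800090307677,2.09999999999991,4,TRUE,TRUE
71,NA,NA,NA,FALSE,FALSE
72,1.51326651923637,1.9666666666667,4,TRUE,TRUE
73,NA,NA,NA,FALSE,FALSE
74,NA,NA,NA,FALSE,FALSE
75,NA,NA,NA,FALSE,FALSE
76,NA,NA,NA,FALSE,FALSE
77,1.72893339873463,2.19999999999982,NA,TRUE,FALSE
78,NA,NA,NA,FALSE,FALSE
79,NA,NA,NA,FALSE,FALSE
80,NA,NA,NA,FALSE,FALSE
81,NA,NA,NA,FALSE,FALSE
82,NA,NA,NA,FALSE,FALSE
83,NA,NA,NA,FALSE,FALSE
84,1.65345778324127,2.09922221001852,NA,TRUE,FALSE
85,NA,NA,NA,FALSE,FALSE
86,NA,NA,NA,FALSE,FALSE
87,NA,NA,NA,FALSE,FALSE
88,NA,NA,NA,FALSE,FALSE
89,NA,NA,NA,FALSE,FALSE
90,1.64612560008482,2.09999999999991,4,TRUE,TRUE
91,NA,NA,NA,FALSE,FALSE
92,NA,NA,NA,FALSE,FALSE
93,NA,NA,NA,FALSE,FALSE
94,1.6198065091894,2.09298387185345,NA,TRUE,FALSE
95,1.70984980189678,2.17687220663447,NA,TRUE,FALSE
96,NA,NA,NA,FALSE,FALSE
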