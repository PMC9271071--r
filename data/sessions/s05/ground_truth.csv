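"trial","approach_init","arrival","drink_time","approach","drink"
1,1.50292220014441,1.96666666666667,4,TRUE,TRUE
2,1.3617753262763,1.83333333333333,4,TRUE,TRUE
3,1.43883889252501,1.90000000000001,4,TRUE,TRUE
4,1.43661751548709,1.89679877264425,NA,TRUE,FALSE
5,1.53249667858367,1.99880199062949,NA,TRUE,FALSE
6,1.55410449050302,2,4,TRUE,TRUE
7,1.32598841833351,1.80557766860971,NA,TRUE,FALSE
8,1.41396776328799,1.86666666666667,4,TRUE,TRUE
9,1.39960257695265,1.85667210314421,NA,TRUE,FALSE
10,1.3272605643179,1.76666666666665,4,TRUE,TRUE
11,1.58598064889219,2.06567791483053,NA,TRUE,FALSE
12,1.52174911138042,2,NA,TRUE,FALSE
13,1.47580148577373,1.93333333333334,4,TRUE,TRUE
14,1.29663630825519,1.76666666666665,4,TRUE,TRUE
15,1.32569038636041,1.79591423726333,NA,TRUE,FALSE
16,1.24607154472881,1.70000000000005,4,TRUE,TRUE
17,1.23895237054444,1.70679502381631,NA,TRUE,FALSE
18,1.40038526306353,1.86225511971861,NA,TRUE,FALSE
19,NA,NA,NA,FALSE,FALSE
20,1.56932586048435,2.03714716580384,NA,TRUE,FALSE
21,1.45021892404952,1.89999999999998,4,TRUE,TRUE
22,1.45743488682103,1.92863430967554,NA,TRUE,FALSE
23,1.40194388221289,1.86666666666667,NA,TRUE,FALSE
24,1.30615221100425,1.76483010711763,NA,TRUE,FALSE
25,1.38921186108848,1.86666666666667,4,TRUE,TRUE
26,1.36147330797758,1.83333333333337,4,TRUE,TRUE
27,1.57980372434201,2.0333333333333,4,TRUE,TRUE
28,1.37823547063363,1.83632712389033,NA,TRUE,FALSE
29,1.53120233806749,2,4,TRUE,TRUE
30,1.31493126598912,1.77255455100294,NA,TRUE,FALSE
31,1.43842931391305,1.89650443888581,NA,TRUE,FALSE
32,1.22240499979875,1.69152634575335,NA,TRUE,FALSE
33,1.55812484229932,2.0333333333333,4,TRUE,TRUE
34,1.37005242851865,1.83333333333326,NA,TRUE,FALSE
35,NA,NA,NA,FALSE,FALSE
36,1.53230933589475,2.01126436324171,NA,TRUE,FALSE
37,1.32937397520936,1.78860422357297,NA,TRUE,FALSE
38,1.42466881499854,1.86666666666656,4,TRUE,TRUE
39,1.50049183179226,1.97257995245354,NA,TRUE,FALSE
40,1.49157640956059,1.93333333333339,4,TRUE,TRUE
41,NA,NA,NA,FALSE,FALSE
42,1.41783175780893,1.90000000000009,4,TRUE,TRUE
43,1.25638233038217,1.71713250453263,NA,TRUE,FALSE
44,1.47049365460043,1.94170981664206,NA,TRUE,FALSE
45,1.43193429728353,1.90000000000009,NA,TRUE,FALSE
46,1.57774082195579,2.02718243086701,NA,TRUE,FALSE
47,1.20430366336313,1.68565682256599,NA,TRUE,FALSE
48,NA,NA,NA,FALSE,FALSE
49,NA,NA,NA,FALSE,FALSE
50,1.38668106671162,1.86107343407343,NA,TRUE,FALSE
51,1.29777572356443,1.75972298206761,NA,TRUE,FALSE
52,1.52952172633877,1.99306324214353,NA,TRUE,FALSE
53,1.39554284829046,1.86666666666656,4,TRUE,TRUE
54,NA,NA,NA,FALSE,FALSE
55,NA,NA,NA,FALSE,FALSE
56,NA,NA,NA,FALSE,FALSE
57,NA,NA,NA,FALSE,FALSE
58,1.40251987942452,1.86666666666656,4,TRUE,TRUE
59,NA,NA,NA,FALSE,FALSE
60,NA,NA,NA,FALSE,FALSE
61,NA,NA,NA,FALSE,FALSE
62,1.40960547550958,1.88989013961191,NA,TRUE,FALSE
63,NA,NA,NA,FALSE,FALSE
64,NA,NA,NA,FALSE,FALSE
65,NA,NA,NA,FALSE,FALSE
66,NA,NA,NA,FALSE,FALSE
67,NA,NA,NA,FALSE,FALSE
68,NA,NA,NA,FALSE,FALSE
69,NA,NA,NA,FALSE,FALSE
70,NA,NA,NA,FALSE,FALSE
71,1.36360433581694,1.83333333333348,4,TRUE,TRUE
72,NA,NA,NA,FALSE,FALSE
73,NA,NA,NA,FALSE,FALSE
74,NA,NA,NA,FALSE,FALSE
75,NA,NA,NA,FALSE,FALSE
76,1.50038842922959,1.96457892643912,NA,TRUE,FALSE
77,NA,NA,NA,FALSE,FALSE
78,NA,NA,NA,FALSE,FALSE
79,NA,NA,NA,FALSE,FALSE
80,NA,NA,NA,FALSE,FALSE
81,NA,NA,NA,FALSE,FALSE
82,NA,NA,NA,FALSE,FALSE
83,NA,NA,NA,FALSE,FALSE
84,1.31924175274162,1.76040513142925,NA,TRUE,FALSE
85,NA,NA,NA,FALSE,FALSE
86,NA,NA,NA,FALSE,FALSE
87,NA,NA,NA,FALSE,FALSE
88,NA,NA,NA,FALSE,FALSE
89,1.3427155068639,1.80000000000018,4,TRUE,TRUE
90,NA,NA,NA,FALSE,FALSE
91,NA,NA,NA,FALSE,FALSE
92,NA,NA,NA,FALSE,FALSE
93,NA,NA,NA,FALSE,FALSE
94,1.3752046140894,1.83333333333348,4,TRUE,TRUE
95,NA,NA,NA,FALSE,FALSE
96,NA,NA,NA,FALSE,FALSE
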