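"trial","approach_init","arrival","drink_time","approach","drink"
1,1.59125268056369,2.04207377706965,NA,TRUE,FALSE
2,1.59088872855232,2.04549684176842,NA,TRUE,FALSE
3,1.46928187226273,1.93333333333333,4,TRUE,TRUE
4,1.45746242217793,1.9319130750373,NA,TRUE,FALSE
5,1.57116874439809,2.01522516263649,NA,TRUE,FALSE
6,1.65129655692328,2.10737878344953,NA,TRUE,FALSE
7,1.50956482087795,1.98840395463631,NA,TRUE,FALSE
8,1.55477148453595,2,4,TRUE,TRUE
9,1.62429173748926,2.10099759474396,NA,TRUE,FALSE
10,1.40336973168792,1.86666666666667,NA,TRUE,FALSE
11,1.48500507196539,1.95088596042865,NA,TRUE,FALSE
12,NA,NA,NA,FALSE,FALSE
13,1.58114722221578,2.03333333333333,4,TRUE,TRUE
14,1.55994023634503,2.0420432502404,NA,TRUE,FALSE
15,1.59398473567643,2.06666666666666,4,TRUE,TRUE
16,NA,NA,NA,FALSE,FALSE
17,1.5668655752321,2.0333333333333,4,TRUE,TRUE
18,1.481157737491,1.95360980549208,NA,TRUE,FALSE
19,1.65580131865948,2.13613067076852,NA,TRUE,FALSE
20,1.40915355562333,1.88460505772383,NA,TRUE,FALSE
21,1.59359122879079,2.06666666666666,4,TRUE,TRUE
22,1.62922920172463,2.09952689126754,NA,TRUE,FALSE
23,1.50743364152794,1.96242299020912,NA,TRUE,FALSE
24,1.36612942182722,1.83333333333331,4,TRUE,TRUE
25,1.38446129560668,1.83333333333337,4,TRUE,TRUE
26,1.53784489278814,1.99109447098647,NA,TRUE,FALSE
27,1.54109773980736,2,4,TRUE,TRUE
28,1.55221699816718,2,4,TRUE,TRUE
29,1.59598746306267,2.06285876824211,NA,TRUE,FALSE
30,1.45452304315552,1.92131946884717,NA,TRUE,FALSE
31,1.49878303120033,1.9666666666667,4,TRUE,TRUE
32,1.39089069051704,1.84423336520172,NA,TRUE,FALSE
33,1.70387170830975,2.16666666666663,4,TRUE,TRUE
34,1.64934904551217,2.10000000000002,4,TRUE,TRUE
35,1.47940565661463,1.93333333333328,4,TRUE,TRUE
36,1.6433283711707,2.10000000000002,4,TRUE,TRUE
37,1.54571286901614,2,4,TRUE,TRUE
38,1.35920557802342,1.83333333333326,4,TRUE,TRUE
39,1.63920079331911,2.11369947713479,NA,TRUE,FALSE
40,1.71083987416114,2.16666666666674,4,TRUE,TRUE
41,1.66786995351163,2.13372742580259,NA,TRUE,FALSE
42,1.66248623775687,2.13333333333321,4,TRUE,FALSE
43,1.46016768361187,1.93324045057716,NA,TRUE,FALSE
44,1.51739341267694,1.9666666666667,4,TRUE,TRUE
45,1.61590894263418,2.06666666666661,4,TRUE,TRUE
46,1.56252721297642,2.0333333333333,4,TRUE,TRUE
47,1.52945908680272,2,4,TRUE,TRUE
48,1.55073440204046,2.00021505939458,NA,TRUE,FALSE
49,1.56702291348279,2.04952789672348,NA,TRUE,FALSE
50,NA,NA,NA,FALSE,FALSE
51,1.41390182319151,1.86666666666656,NA,TRUE,FALSE
52,NA,NA,NA,FALSE,FALSE
53,NA,NA,NA,FALSE,FALSE
54,NA,NA,NA,FALSE,FALSE
55,NA,NA,NA,FALSE,FALSE
56,NA,NA,NA,FALSE,FALSE
57,1.47869144557626,1.93047956110286,NA,TRUE,FALSE
58,1.39688081402483,1.85163646716001,NA,TRUE,FALSE
59,NA,NA,NA,FALSE,FALSE
60,NA,NA,NA,FALSE,FALSE
61,NA,NA,NA,FALSE,FALSE
62,1.4746308204069,1.93333333333339,4,TRUE,TRUE
63,NA,NA,NA,FALSE,FALSE
64,NA,NA,NA,FALSE,FALSE
65,NA,NA,NA,FALSE,FALSE
66,NA,NA,NA,FALSE,FALSE
67,1.62906008326445,2.09999999999991,4,TRUE,TRUE
68,NA,NA,NA,FALSE,FALSE
69,NA,NA,NA,FALSE,FALSE
70,NA,NA,NA,FALSE,FALSE
71,1.55581810781223,2.0333333333333,4,TRUE,TRUE
72,1.49491295667713,1.96821219539288,NA,TRUE,FALSE
73,NA,NA,NA,FALSE,FALSE
74,NA,NA,NA,FALSE,FALSE
75,1.6012162225652,2.06666666666661,4,TRUE,TRUE
76,1.43607751196578,1.90256088565411,NA,TRUE,FALSE
77,NA,NA,NA,FALSE,FALSE
78,NA,NA,NA,FALSE,FALSE
79,1.40402345744042,1.86666666666679,4,TRUE,TRUE
80,NA,NA,NA,FALSE,FALSE
81,NA,NA,NA,FALSE,FALSE
82,1.7975236285356,2.26666666666642,4,TRUE,TRUE
83,NA,NA,NA,FALSE,FALSE
84,1.647494262495,2.09999999999991,4,TRUE,TRUE
85,NA,NA,NA,FALSE,FALSE
86,1.58783188952384,2.06666666666661,4,TRUE,TRUE
87,NA,NA,NA,FALSE,FALSE
88,NA,NA,NA,FALSE,FALSE
89,NA,NA,NA,FALSE,FALSE
90,NA,NA,NA,FALSE,FALSE
91,NA,NA,NA,FALSE,FALSE
92,NA,NA,NA,FALSE,FALSE
93,1.47364545768551,1.9550307375066,NA,TRUE,FALSE
94,NA,NA,NA,FALSE,FALSE
95,1.55457778853179,2.00035033455742,NA,TRUE,FALSE
96,NA,NA,NA,FALSE,FALSE
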