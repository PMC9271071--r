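"trial","approach_init","arrival","drink_time","approach","drink"
1,0.999990201802651,1.45817852802575,NA,TRUE,FALSE
2,0.98807306376014,1.46666666666667,4,TRUE,TRUE
3,1.17354018510518,1.63333333333333,4,TRUE,TRUE
4,1.18980868362723,1.63333333333333,4,TRUE,TRUE
5,1.14535072655676,1.60147868258258,NA,TRUE,FALSE
6,NA,NA,NA,FALSE,FALSE
7,1.11928427250535,1.58783625690265,NA,TRUE,FALSE
8,NA,NA,NA,FALSE,FALSE
9,1.18120455190953,1.64907739097251,NA,TRUE,FALSE
10,0.92002820192431,1.39999999999998,4,TRUE,FALSE
11,0.863099776092213,1.32885150065022,NA,TRUE,FALSE
12,1.13484200797859,1.60000000000002,4,TRUE,FALSE
13,0.98932916641246,1.44281270609548,NA,TRUE,FALSE
14,0.859242874883989,1.33333333333331,NA,TRUE,FALSE
15,1.0688641101259,1.5333333333333,4,TRUE,TRUE
16,NA,NA,NA,FALSE,FALSE
17,1.06642369421689,1.5116284055635,NA,TRUE,FALSE
18,1.15314915384351,1.62426045744991,NA,TRUE,FALSE
19,1.09955386168474,1.56666666666666,4,TRUE,TRUE
20,0.895425428120348,1.37133717453105,NA,TRUE,FALSE
21,NA,NA,NA,FALSE,FALSE
22,1.01617397454095,1.46972714435924,NA,TRUE,FALSE
23,1.2142075616249,1.66666666666663,4,TRUE,TRUE
24,0.986321820496414,1.4666666666667,4,TRUE,TRUE
25,0.991884671394473,1.45901982079567,NA,TRUE,FALSE
26,0.896050841950341,1.34918305687609,NA,TRUE,FALSE
27,1.09886452767114,1.56666666666661,NA,TRUE,FALSE
28,1.25129879541043,1.70888798429314,NA,TRUE,FALSE
29,NA,NA,NA,FALSE,FALSE
30,0.987310870530905,1.43413107028846,NA,TRUE,FALSE
31,0.971361626873318,1.45174495850995,NA,TRUE,FALSE
32,1.12439063742113,1.59734636228529,NA,TRUE,FALSE
33,0.909347402242133,1.36666666666667,NA,TRUE,FALSE
34,0.886721101108492,1.34793678311007,NA,TRUE,FALSE
35,0.856548204693809,1.33333333333337,4,TRUE,TRUE
36,0.869677777824791,1.33333333333337,NA,TRUE,FALSE
37,1.09629765798297,1.56666666666661,NA,TRUE,FALSE
38,1.05497180292423,1.5333333333333,4,TRUE,TRUE
39,1.08303145948912,1.55331434579557,NA,TRUE,FALSE
40,0.904193562301089,1.36666666666656,4,TRUE,TRUE
41,1.02149349110778,1.5,4,TRUE,TRUE
42,1.18337796389937,1.63333333333321,NA,TRUE,FALSE
43,0.983698785831848,1.44547274988145,NA,TRUE,FALSE
44,0.790387988770817,1.23333333333335,4,TRUE,TRUE
45,0.925719937207987,1.36666666666656,4,TRUE,TRUE
46,0.90771427114305,1.38085782366488,NA,TRUE,FALSE
47,1.01153425702546,1.46134692551573,NA,TRUE,FALSE
48,NA,NA,NA,FALSE,FALSE
49,1.03098459532771,1.5,4,TRUE,TRUE
50,1.08002938122581,1.5333333333333,4,TRUE,TRUE
51,NA,NA,NA,FALSE,FALSE
52,NA,NA,NA,FALSE,FALSE
53,0.9020687855907,1.35827301985887,NA,TRUE,FALSE
54,NA,NA,NA,FALSE,FALSE
55,NA,NA,NA,FALSE,FALSE
56,0.940169291057373,1.39796655693408,NA,TRUE,FALSE
57,NA,NA,NA,FALSE,FALSE
58,0.888408646982043,1.34380992262936,NA,TRUE,FALSE
59,NA,NA,NA,FALSE,FALSE
60,1.10996547200534,1.56666666666661,4,TRUE,TRUE
61,NA,NA,NA,FALSE,FALSE
62,NA,NA,NA,FALSE,FALSE
63,NA,NA,NA,FALSE,FALSE
64,NA,NA,NA,FALSE,FALSE
65,NA,NA,NA,FALSE,FALSE
66,NA,NA,NA,FALSE,FALSE
67,NA,NA,NA,FALSE,FALSE
68,NA,NA,NA,FALSE,FALSE
69,0.96537023165547,1.43333333333339,4,TRUE,TRUE
70,NA,NA,NA,FALSE,FALSE
71,1.14498162574364,1.61132781698052,NA,TRUE,FALSE
72,1.11296271351875,1.56666666666661,4,TRUE,TRUE
73,0.95119199288456,1.41977979764351,NA,TRUE,FALSE
74,NA,NA,NA,FALSE,FALSE
75,NA,NA,NA,FALSE,FALSE
76,NA,NA,NA,FALSE,FALSE
77,NA,NA,NA,FALSE,FALSE
78,NA,NA,NA,FALSE,FALSE
79,NA,NA,NA,FALSE,FALSE
80,NA,NA,NA,FALSE,FALSE
81,NA,NA,NA,FALSE,FALSE
82,NA,NA,NA,FALSE,FALSE
83,0.947037144023398,1.39451991077522,NA,TRUE,FALSE
84,NA,NA,NA,FALSE,FALSE
85,NA,NA,NA,FALSE,FALSE
86,NA,NA,NA,FALSE,FALSE
87,NA,NA,NA,FALSE,FALSE
88,NA,NA,NA,FALSE,FALSE
89,NA,NA,NA,FALSE,FALSE
90,NA,NA,NA,FALSE,FALSE
91,1.03557887559009,1.5,NA,TRUE,FALSE
92,NA,NA,NA,FALSE,FALSE
93,0.992697210921506,1.43333333333339,4,TRUE,TRUE
94,NA,NA,NA,FALSE,FALSE
95,NA,NA,NA,FALSE,FALSE
96,NA,NA,NA,FALSE,FALSE
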