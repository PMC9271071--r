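"trial","cs_type","cs_index","side","cs_onset","approach","correct","drink","approach_side"
1,"plus",1,"right",30,TRUE,TRUE,TRUE,"right"
2,"plus",2,"right",110,TRUE,TRUE,TRUE,"right"
3,"plus",3,"left",166,TRUE,TRUE,TRUE,"left"
4,"minus",1,NA,197.203201227356,TRUE,FALSE,FALSE,"left"
5,"minus",2,NA,207.934531342704,TRUE,FALSE,FALSE,"left"
6,"plus",4,"right",246,TRUE,TRUE,TRUE,"right"
7,"minus",3,NA,283.761088998057,TRUE,FALSE,FALSE,"left"
8,"plus",5,"left",302,TRUE,TRUE,TRUE,"left"
9,"minus",4,NA,319.543327896856,TRUE,FALSE,FALSE,"left"
10,"plus",6,"right",358,TRUE,TRUE,TRUE,"right"
11,"minus",5,NA,385.700988751836,TRUE,FALSE,FALSE,"left"
12,"plus",7,"right",406,TRUE,FALSE,FALSE,"left"
13,"plus",8,"left",438,TRUE,TRUE,TRUE,"left"
14,"plus",9,"left",570,TRUE,TRUE,TRUE,"left"
15,"minus",6,NA,595.670752429403,TRUE,FALSE,FALSE,"left"
16,"plus",10,"left",610,TRUE,TRUE,TRUE,"left"
17,"minus",7,NA,639.55987164285,TRUE,FALSE,FALSE,"left"
18,"minus",8,NA,653.137744880281,TRUE,FALSE,FALSE,"left"
19,"plus",11,"right",666,FALSE,FALSE,FALSE,NA
20,"minus",9,NA,683.229519500863,TRUE,FALSE,FALSE,"right"
21,"plus",12,"right",714,TRUE,TRUE,TRUE,"right"
22,"minus",10,NA,773.071365690324,TRUE,FALSE,FALSE,"left"
23,"plus",13,"left",846,TRUE,FALSE,FALSE,"right"
24,"minus",11,NA,866.801836559549,TRUE,FALSE,FALSE,"left"
25,"plus",14,"left",878,TRUE,TRUE,TRUE,"left"
26,"plus",15,"left",918,TRUE,TRUE,TRUE,"left"
27,"plus",16,"left",986,TRUE,TRUE,TRUE,"left"
28,"minus",12,NA,1020.03033954278,TRUE,FALSE,FALSE,"left"
29,"plus",17,"left",1042,TRUE,TRUE,TRUE,"left"
30,"minus",13,NA,1082.16077878233,TRUE,FALSE,FALSE,"right"
31,"minus",14,NA,1117.83682889445,TRUE,FALSE,FALSE,"left"
32,"minus",15,NA,1137.64180698758,TRUE,FALSE,FALSE,"left"
33,"plus",18,"left",1150,TRUE,TRUE,TRUE,"left"
34,"plus",19,"right",1258,TRUE,FALSE,FALSE,"left"
35,"plus",20,"right",1290,FALSE,FALSE,FALSE,NA
36,"minus",16,NA,1309.22206897009,TRUE,FALSE,FALSE,"left"
37,"minus",17,NA,1320.94472910976,TRUE,FALSE,FALSE,"right"
38,"plus",21,"right",1330,TRUE,TRUE,TRUE,"right"
39,"minus",18,NA,1351.06075338088,TRUE,FALSE,FALSE,"right"
40,"plus",22,"right",1410,TRUE,TRUE,TRUE,"right"
41,"minus",19,NA,1463.91800590931,FALSE,FALSE,FALSE,NA
42,"plus",23,"left",1518,TRUE,TRUE,TRUE,"left"
43,"minus",20,NA,1553.64953416213,TRUE,FALSE,FALSE,"left"
44,"minus",21,NA,1615.35829018336,TRUE,FALSE,FALSE,"right"
45,"plus",24,"left",1626,TRUE,FALSE,FALSE,"right"
46,"minus",22,NA,1648.07281756913,TRUE,FALSE,FALSE,"right"
47,"minus",23,NA,1667.01434317743,TRUE,FALSE,FALSE,"left"
48,"plus",25,"right",1682,FALSE,FALSE,FALSE,NA
49,"minus",24,NA,1707.63512564916,FALSE,FALSE,FALSE,NA
50,"minus",25,NA,1712.93892656593,TRUE,FALSE,FALSE,"right"
51,"minus",26,NA,1723.24027701793,TRUE,FALSE,FALSE,"left"
52,"minus",27,NA,1729.87360342452,TRUE,FALSE,FALSE,"right"
53,"plus",26,"right",1738,TRUE,TRUE,TRUE,"right"
54,"plus",27,"right",1806,FALSE,FALSE,FALSE,NA
55,"plus",28,"right",1862,FALSE,FALSE,FALSE,NA
56,"plus",29,"right",1930,FALSE,FALSE,FALSE,NA
57,"minus",28,NA,1955.12780258525,FALSE,FALSE,FALSE,NA
58,"plus",30,"left",1986,TRUE,TRUE,TRUE,"left"
59,"minus",29,NA,2066.05855106749,FALSE,FALSE,FALSE,NA
60,"plus",31,"right",2118,FALSE,FALSE,FALSE,NA
61,"minus",30,NA,2137.56780016841,FALSE,FALSE,FALSE,NA
62,"minus",31,NA,2175.77677652705,TRUE,FALSE,FALSE,"left"
63,"plus",32,"left",2186,FALSE,FALSE,FALSE,NA
64,"minus",32,NA,2205.74111150485,FALSE,FALSE,FALSE,NA
65,"minus",33,NA,2217.15094533283,FALSE,FALSE,FALSE,NA
66,"plus",33,"right",2242,FALSE,FALSE,FALSE,NA
67,"minus",34,NA,2258.19100200292,FALSE,FALSE,FALSE,NA
68,"minus",35,NA,2279.41217458015,FALSE,FALSE,FALSE,NA
69,"plus",34,"right",2350,FALSE,FALSE,FALSE,NA
70,"minus",36,NA,2370.84959553136,FALSE,FALSE,FALSE,NA
71,"plus",35,"right",2398,TRUE,TRUE,TRUE,"right"
72,"plus",36,"right",2478,FALSE,FALSE,FALSE,NA
73,"minus",37,NA,2496.71952298889,FALSE,FALSE,FALSE,NA
74,"minus",38,NA,2516.34886518447,FALSE,FALSE,FALSE,NA
75,"minus",39,NA,2525.69292249158,FALSE,FALSE,FALSE,NA
76,"minus",40,NA,2551.00208774023,TRUE,FALSE,FALSE,"left"
77,"plus",37,"left",2586,FALSE,FALSE,FALSE,NA
78,"minus",41,NA,2645.51158792619,FALSE,FALSE,FALSE,NA
79,"plus",38,"left",2654,FALSE,FALSE,FALSE,NA
80,"minus",42,NA,2671.5542959501,FALSE,FALSE,FALSE,NA
81,"plus",39,"left",2786,FALSE,FALSE,FALSE,NA
82,"plus",40,"left",2894,FALSE,FALSE,FALSE,NA
83,"plus",41,"right",2962,FALSE,FALSE,FALSE,NA
84,"minus",43,NA,2998.93959486857,TRUE,FALSE,FALSE,"right"
85,"plus",42,"left",3042,FALSE,FALSE,FALSE,NA
86,"minus",44,NA,3085.90501626953,FALSE,FALSE,FALSE,NA
87,"minus",45,NA,3101.28721214039,FALSE,FALSE,FALSE,NA
88,"plus",43,"right",3150,FALSE,FALSE,FALSE,NA
89,"plus",44,"right",3218,TRUE,TRUE,TRUE,"right"
90,"minus",46,NA,3239.90393041493,FALSE,FALSE,FALSE,NA
91,"minus",47,NA,3249.99586472474,FALSE,FALSE,FALSE,NA
92,"plus",45,"left",3266,FALSE,FALSE,FALSE,NA
93,"minus",48,NA,3294.67494606879,FALSE,FALSE,FALSE,NA
94,"plus",46,"left",3306,TRUE,TRUE,TRUE,"left"
95,"plus",47,"left",3386,FALSE,FALSE,FALSE,NA
96,"plus",48,"left",3518,FALSE,FALSE,FALSE,NA
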