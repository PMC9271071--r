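"trial","cs_type","cs_index","side","cs_onset","approach","correct","drink","approach_side"
1,"minus",1,NA,11.6418214719743,TRUE,FALSE,FALSE,"right"
2,"plus",1,"right",30,TRUE,TRUE,TRUE,"right"
3,"plus",2,"right",110,TRUE,TRUE,TRUE,"right"
4,"plus",3,"left",178,TRUE,TRUE,TRUE,"left"
5,"minus",2,NA,207.331854650751,TRUE,FALSE,FALSE,"left"
6,"plus",4,"left",226,FALSE,FALSE,FALSE,NA
7,"minus",3,NA,241.212163743097,TRUE,FALSE,FALSE,"right"
8,"minus",4,NA,245.309072670061,FALSE,FALSE,FALSE,NA
9,"minus",5,NA,250.650922609027,TRUE,FALSE,FALSE,"right"
10,"plus",5,"right",258,TRUE,TRUE,FALSE,"right"
11,"minus",6,NA,274.204481832683,TRUE,FALSE,FALSE,"left"
12,"plus",6,"right",298,TRUE,TRUE,FALSE,"right"
13,"minus",7,NA,319.490520627238,TRUE,FALSE,FALSE,"right"
14,"plus",7,"right",338,TRUE,FALSE,FALSE,"left"
15,"plus",8,"right",418,TRUE,TRUE,TRUE,"right"
16,"minus",8,NA,433.25764803635,FALSE,FALSE,FALSE,NA
17,"minus",9,NA,438.088371594436,TRUE,FALSE,FALSE,"left"
18,"minus",10,NA,442.309072875883,TRUE,FALSE,FALSE,"right"
19,"plus",9,"left",450,TRUE,TRUE,TRUE,"left"
20,"minus",11,NA,483.528662825469,TRUE,FALSE,FALSE,"right"
21,"minus",12,NA,512.511962513905,FALSE,FALSE,FALSE,NA
22,"minus",13,NA,537.596939522307,TRUE,FALSE,FALSE,"right"
23,"plus",10,"right",582,TRUE,TRUE,TRUE,"right"
24,"plus",11,"right",638,TRUE,TRUE,TRUE,"right"
25,"minus",14,NA,657.074313512538,TRUE,FALSE,FALSE,"left"
26,"minus",15,NA,686.750816943124,TRUE,FALSE,FALSE,"right"
27,"plus",12,"right",694,TRUE,FALSE,FALSE,"left"
28,"minus",16,NA,734.357778682373,TRUE,FALSE,FALSE,"right"
29,"minus",17,NA,757.143582226243,FALSE,FALSE,FALSE,NA
30,"minus",18,NA,762.632535596378,TRUE,FALSE,FALSE,"left"
31,"minus",19,NA,778.981588374823,TRUE,FALSE,FALSE,"right"
32,"minus",20,NA,786.802653637715,TRUE,FALSE,FALSE,"right"
33,"plus",13,"right",802,TRUE,FALSE,FALSE,"left"
34,"minus",21,NA,822.185396550223,TRUE,FALSE,FALSE,"right"
35,"plus",14,"right",850,TRUE,TRUE,TRUE,"right"
36,"plus",15,"right",906,TRUE,FALSE,FALSE,"left"
37,"plus",16,"left",986,TRUE,FALSE,FALSE,"right"
38,"plus",17,"right",1094,TRUE,TRUE,TRUE,"right"
39,"minus",22,NA,1161.0466856542,TRUE,FALSE,FALSE,"right"
40,"plus",18,"left",1226,TRUE,TRUE,TRUE,"left"
41,"plus",19,"right",1266,TRUE,TRUE,TRUE,"right"
42,"plus",20,"right",1298,TRUE,FALSE,FALSE,"left"
43,"minus",23,NA,1314.55452725012,TRUE,FALSE,FALSE,"left"
44,"plus",21,"left",1338,TRUE,TRUE,TRUE,"left"
45,"plus",22,"left",1378,TRUE,TRUE,TRUE,"left"
46,"minus",24,NA,1399.185808843,TRUE,FALSE,FALSE,"right"
47,"minus",25,NA,1410.73865307448,TRUE,FALSE,FALSE,"left"
48,"minus",26,NA,1431.40325671062,FALSE,FALSE,FALSE,NA
49,"plus",23,"left",1446,TRUE,TRUE,TRUE,"left"
50,"plus",24,"left",1486,TRUE,TRUE,TRUE,"left"
51,"plus",25,"left",1542,FALSE,FALSE,FALSE,NA
52,"plus",26,"right",1598,FALSE,FALSE,FALSE,NA
53,"minus",27,NA,1646.47506031347,TRUE,FALSE,FALSE,"left"
54,"plus",27,"left",1654,FALSE,FALSE,FALSE,NA
55,"minus",28,NA,1678.54661917174,FALSE,FALSE,FALSE,NA
56,"minus",29,NA,1690.0353667764,TRUE,FALSE,FALSE,"left"
57,"minus",30,NA,1702.57641789736,FALSE,FALSE,FALSE,NA
58,"minus",31,NA,1711.8895234107,TRUE,FALSE,FALSE,"right"
59,"plus",28,"left",1722,FALSE,FALSE,FALSE,NA
60,"plus",29,"right",1790,TRUE,TRUE,TRUE,"right"
61,"plus",30,"right",1830,FALSE,FALSE,FALSE,NA
62,"minus",32,NA,1845.22598853894,FALSE,FALSE,FALSE,NA
63,"plus",31,"left",1878,FALSE,FALSE,FALSE,NA
64,"minus",33,NA,1898.59929570649,FALSE,FALSE,FALSE,NA
65,"plus",32,"left",1934,FALSE,FALSE,FALSE,NA
66,"plus",33,"left",1966,FALSE,FALSE,FALSE,NA
67,"minus",34,NA,1998.41254281532,FALSE,FALSE,FALSE,NA
68,"plus",34,"right",2074,FALSE,FALSE,FALSE,NA
69,"plus",35,"left",2122,TRUE,TRUE,TRUE,"left"
70,"minus",35,NA,2140.4884619005,FALSE,FALSE,FALSE,NA
71,"minus",36,NA,2144.95533884969,TRUE,FALSE,FALSE,"right"
72,"plus",36,"left",2154,TRUE,TRUE,TRUE,"left"
73,"minus",37,NA,2235.48022020236,TRUE,FALSE,FALSE,"right"
74,"plus",37,"right",2262,FALSE,FALSE,FALSE,NA
75,"minus",38,NA,2283.86326640658,FALSE,FALSE,FALSE,NA
76,"plus",38,"left",2394,FALSE,FALSE,FALSE,NA
77,"plus",39,"right",2434,FALSE,FALSE,FALSE,NA
78,"minus",39,NA,2459.37880176818,FALSE,FALSE,FALSE,NA
79,"minus",40,NA,2464.01052508736,FALSE,FALSE,FALSE,NA
80,"plus",40,"right",2474,FALSE,FALSE,FALSE,NA
81,"minus",41,NA,2497.99536431069,FALSE,FALSE,FALSE,NA
82,"plus",41,"right",2506,FALSE,FALSE,FALSE,NA
83,"minus",42,NA,2529.00548008922,TRUE,FALSE,FALSE,"left"
84,"plus",42,"right",2546,FALSE,FALSE,FALSE,NA
85,"minus",43,NA,2585.33818385145,FALSE,FALSE,FALSE,NA
86,"plus",43,"left",2614,FALSE,FALSE,FALSE,NA
87,"minus",44,NA,2670.42466885829,FALSE,FALSE,FALSE,NA
88,"plus",44,"right",2722,FALSE,FALSE,FALSE,NA
89,"minus",45,NA,2741.26215220103,FALSE,FALSE,FALSE,NA
90,"minus",46,NA,2745.3752994719,FALSE,FALSE,FALSE,NA
91,"plus",45,"left",2762,TRUE,FALSE,FALSE,"right"
92,"minus",47,NA,2799.12543390458,FALSE,FALSE,FALSE,NA
93,"plus",46,"left",2810,TRUE,TRUE,TRUE,"left"
94,"minus",48,NA,2881.46607110975,FALSE,FALSE,FALSE,NA
95,"plus",47,"left",2942,FALSE,FALSE,FALSE,NA
96,"plus",48,"right",3050,FALSE,FALSE,FALSE,NA
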