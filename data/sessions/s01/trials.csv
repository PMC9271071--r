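"trial","cs_type","cs_index","side","cs_onset","approach","correct","drink","approach_side"
1,"minus",1,NA,6.30183774698526,TRUE,FALSE,FALSE,"right"
2,"plus",1,"right",30,TRUE,TRUE,TRUE,"right"
3,"plus",2,"right",138,TRUE,TRUE,TRUE,"right"
4,"minus",2,NA,177.63004614599,TRUE,FALSE,FALSE,"left"
5,"minus",3,NA,246.64427575469,TRUE,FALSE,FALSE,"left"
6,"minus",4,NA,251.735985973384,TRUE,FALSE,FALSE,"left"
7,"minus",5,NA,261.264147145208,TRUE,FALSE,FALSE,"left"
8,"plus",3,"left",270,TRUE,TRUE,TRUE,"left"
9,"minus",6,NA,334.145556172822,FALSE,FALSE,FALSE,NA
10,"plus",4,"right",350,TRUE,TRUE,TRUE,"right"
11,"minus",7,NA,388.606138393283,FALSE,FALSE,FALSE,NA
12,"minus",8,NA,409.242197904736,TRUE,FALSE,FALSE,"left"
13,"minus",9,NA,424.48742739344,FALSE,FALSE,FALSE,NA
14,"plus",5,"right",458,FALSE,FALSE,FALSE,NA
15,"minus",10,NA,514.639268348925,TRUE,FALSE,FALSE,"left"
16,"plus",6,"left",526,TRUE,TRUE,TRUE,"left"
17,"minus",11,NA,551.658812564798,FALSE,FALSE,FALSE,NA
18,"plus",7,"right",582,TRUE,TRUE,TRUE,"right"
19,"plus",8,"right",638,TRUE,TRUE,TRUE,"right"
20,"minus",12,NA,706.209055554587,TRUE,FALSE,FALSE,"right"
21,"plus",9,"left",718,TRUE,TRUE,TRUE,"left"
22,"minus",13,NA,737.115519197658,FALSE,FALSE,FALSE,NA
23,"minus",14,NA,741.675265573896,TRUE,FALSE,FALSE,"left"
24,"minus",15,NA,748.289461893961,TRUE,FALSE,FALSE,"left"
25,"plus",10,"right",758,TRUE,TRUE,TRUE,"right"
26,"plus",11,"left",806,FALSE,FALSE,FALSE,NA
27,"minus",16,NA,825.482741296757,TRUE,FALSE,FALSE,"right"
28,"plus",12,"left",854,TRUE,TRUE,TRUE,"left"
29,"minus",17,NA,890.025514407083,FALSE,FALSE,FALSE,NA
30,"plus",13,"left",986,TRUE,TRUE,TRUE,"left"
31,"minus",18,NA,1020.58162724506,TRUE,FALSE,FALSE,"right"
32,"plus",14,"right",1042,TRUE,TRUE,TRUE,"right"
33,"plus",15,"left",1110,TRUE,TRUE,TRUE,"left"
34,"minus",19,NA,1181.34571477538,TRUE,FALSE,FALSE,"right"
35,"plus",16,"left",1242,TRUE,TRUE,TRUE,"left"
36,"plus",17,"left",1350,TRUE,TRUE,TRUE,"left"
37,"plus",18,"right",1418,TRUE,TRUE,TRUE,"right"
38,"plus",19,"right",1450,TRUE,TRUE,FALSE,"right"
39,"minus",20,NA,1473.01385895396,TRUE,FALSE,FALSE,"left"
40,"minus",21,NA,1501.57286692597,FALSE,FALSE,FALSE,NA
41,"plus",20,"left",1518,TRUE,TRUE,TRUE,"left"
42,"plus",21,"right",1650,TRUE,TRUE,TRUE,"right"
43,"plus",22,"left",1730,TRUE,TRUE,TRUE,"left"
44,"plus",23,"left",1810,TRUE,FALSE,FALSE,"right"
45,"minus",22,NA,1829.66043297527,TRUE,FALSE,FALSE,"right"
46,"minus",23,NA,1876.80130548682,TRUE,FALSE,FALSE,"right"
47,"plus",24,"right",1918,FALSE,FALSE,FALSE,NA
48,"plus",25,"left",1950,FALSE,FALSE,FALSE,NA
49,"minus",24,NA,1980.52533231955,FALSE,FALSE,FALSE,NA
50,"minus",25,NA,1994.54279286508,FALSE,FALSE,FALSE,NA
51,"plus",26,"left",2018,TRUE,TRUE,TRUE,"left"
52,"minus",26,NA,2039.31785437698,FALSE,FALSE,FALSE,NA
53,"plus",27,"left",2050,FALSE,FALSE,FALSE,NA
54,"plus",28,"left",2082,FALSE,FALSE,FALSE,NA
55,"plus",29,"left",2138,FALSE,FALSE,FALSE,NA
56,"minus",27,NA,2156.96045540692,FALSE,FALSE,FALSE,NA
57,"minus",28,NA,2190.25580350356,FALSE,FALSE,FALSE,NA
58,"minus",29,NA,2194.88841053238,FALSE,FALSE,FALSE,NA
59,"plus",30,"left",2218,FALSE,FALSE,FALSE,NA
60,"minus",30,NA,2269.06044095801,FALSE,FALSE,FALSE,NA
61,"plus",31,"right",2298,FALSE,FALSE,FALSE,NA
62,"minus",31,NA,2320.35782359261,FALSE,FALSE,FALSE,NA
63,"plus",32,"right",2330,FALSE,FALSE,FALSE,NA
64,"minus",32,NA,2350.0239143311,FALSE,FALSE,FALSE,NA
65,"minus",33,NA,2365.16749671102,TRUE,FALSE,FALSE,"right"
66,"plus",33,"right",2378,FALSE,FALSE,FALSE,NA
67,"plus",34,"left",2510,FALSE,FALSE,FALSE,NA
68,"minus",34,NA,2528.83109417884,FALSE,FALSE,FALSE,NA
69,"minus",35,NA,2543.14144227048,FALSE,FALSE,FALSE,NA
70,"plus",35,"left",2558,FALSE,FALSE,FALSE,NA
71,"minus",36,NA,2588.10081228288,TRUE,FALSE,FALSE,"left"
72,"plus",36,"left",2598,FALSE,FALSE,FALSE,NA
73,"minus",37,NA,2636.92379405349,TRUE,FALSE,FALSE,"right"
74,"plus",37,"right",2646,TRUE,TRUE,TRUE,"right"
75,"minus",38,NA,2667.16803660849,FALSE,FALSE,FALSE,NA
76,"plus",38,"left",2702,FALSE,FALSE,FALSE,NA
77,"minus",39,NA,2728.30736299837,FALSE,FALSE,FALSE,NA
78,"minus",40,NA,2735.90282635763,FALSE,FALSE,FALSE,NA
79,"plus",39,"right",2750,TRUE,TRUE,TRUE,"right"
80,"minus",41,NA,2778.30178747373,TRUE,FALSE,FALSE,"right"
81,"plus",40,"right",2790,TRUE,TRUE,TRUE,"right"
82,"minus",42,NA,2805.11390131759,FALSE,FALSE,FALSE,NA
83,"minus",43,NA,2832.57892106287,FALSE,FALSE,FALSE,NA
84,"plus",41,"right",2858,TRUE,TRUE,TRUE,"right"
85,"minus",44,NA,2876.84248643974,FALSE,FALSE,FALSE,NA
86,"plus",42,"right",2906,FALSE,FALSE,FALSE,NA
87,"plus",43,"left",2974,FALSE,FALSE,FALSE,NA
88,"plus",44,"left",3030,FALSE,FALSE,FALSE,NA
89,"minus",45,NA,3115.6183099472,FALSE,FALSE,FALSE,NA
90,"plus",45,"right",3138,FALSE,FALSE,FALSE,NA
91,"plus",46,"left",3270,FALSE,FALSE,FALSE,NA
92,"plus",47,"left",3326,FALSE,FALSE,FALSE,NA
93,"minus",46,NA,3351.43920095311,FALSE,FALSE,FALSE,NA
94,"minus",47,NA,3373.78559435718,FALSE,FALSE,FALSE,NA
95,"plus",48,"left",3382,FALSE,FALSE,FALSE,NA
96,"minus",48,NA,3420.57436563354,FALSE,FALSE,FALSE,NA
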