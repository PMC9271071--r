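"trial","cs_type","cs_index","side","cs_onset","approach","correct","drink","approach_side"
1,"plus",1,"left",30,TRUE,TRUE,TRUE,"left"
2,"minus",1,NA,46.1818800563924,TRUE,FALSE,FALSE,"left"
3,"minus",2,NA,51.0967381028458,TRUE,FALSE,FALSE,"left"
4,"minus",3,NA,56.3439020230435,FALSE,FALSE,FALSE,NA
5,"minus",4,NA,65.2996140839532,TRUE,FALSE,FALSE,"right"
6,"minus",5,NA,69.8346577063203,TRUE,FALSE,FALSE,"left"
7,"plus",2,"left",78,TRUE,TRUE,TRUE,"left"
8,"plus",3,"right",110,TRUE,TRUE,TRUE,"right"
9,"minus",6,NA,135.402164871339,TRUE,FALSE,FALSE,"left"
10,"plus",4,"left",242,TRUE,TRUE,TRUE,"left"
11,"plus",5,"right",298,TRUE,TRUE,TRUE,"right"
12,"minus",7,NA,418.002552280203,TRUE,FALSE,FALSE,"left"
13,"plus",6,"left",430,FALSE,FALSE,FALSE,NA
14,"plus",7,"left",510,TRUE,TRUE,TRUE,"left"
15,"minus",8,NA,532.398486624006,TRUE,FALSE,FALSE,"left"
16,"plus",8,"right",542,TRUE,TRUE,TRUE,"right"
17,"minus",9,NA,559.653042932507,TRUE,FALSE,FALSE,"left"
18,"plus",9,"left",574,TRUE,TRUE,TRUE,"left"
19,"minus",10,NA,600.280210966244,TRUE,FALSE,FALSE,"left"
20,"plus",10,"left",622,FALSE,FALSE,FALSE,NA
21,"plus",11,"left",670,TRUE,TRUE,TRUE,"left"
22,"minus",11,NA,691.062780344393,TRUE,FALSE,FALSE,"right"
23,"plus",12,"left",710,TRUE,TRUE,TRUE,"left"
24,"minus",12,NA,729.677571773995,TRUE,FALSE,FALSE,"right"
25,"minus",13,NA,739.436008619145,TRUE,FALSE,FALSE,"left"
26,"plus",13,"right",750,TRUE,TRUE,TRUE,"right"
27,"minus",14,NA,777.267440248281,TRUE,FALSE,FALSE,"right"
28,"plus",14,"right",830,TRUE,TRUE,TRUE,"right"
29,"minus",15,NA,848.15706356056,FALSE,FALSE,FALSE,NA
30,"plus",15,"right",878,TRUE,TRUE,TRUE,"right"
31,"minus",16,NA,899.806305190548,TRUE,FALSE,FALSE,"left"
32,"plus",16,"right",910,TRUE,TRUE,TRUE,"right"
33,"plus",17,"left",978,TRUE,TRUE,TRUE,"left"
34,"plus",18,"right",1058,TRUE,TRUE,TRUE,"right"
35,"minus",17,NA,1116.66354751587,TRUE,FALSE,FALSE,"right"
36,"minus",18,NA,1128.37258218275,TRUE,FALSE,FALSE,"left"
37,"plus",19,"left",1138,TRUE,TRUE,TRUE,"left"
38,"plus",20,"left",1246,TRUE,TRUE,TRUE,"left"
39,"minus",19,NA,1261.36556793749,TRUE,FALSE,FALSE,"left"
40,"minus",20,NA,1265.77590338793,FALSE,FALSE,FALSE,NA
41,"minus",21,NA,1270.19333227118,TRUE,FALSE,FALSE,"left"
42,"plus",21,"left",1278,TRUE,TRUE,TRUE,"left"
43,"plus",22,"left",1318,TRUE,TRUE,TRUE,"left"
44,"plus",23,"right",1386,TRUE,TRUE,TRUE,"right"
45,"minus",22,NA,1425.81274361722,TRUE,FALSE,FALSE,"left"
46,"plus",24,"left",1518,TRUE,TRUE,TRUE,"left"
47,"plus",25,"left",1650,FALSE,FALSE,FALSE,NA
48,"minus",23,NA,1678.25942105614,FALSE,FALSE,FALSE,NA
49,"plus",26,"left",1782,FALSE,FALSE,FALSE,NA
50,"minus",24,NA,1827.38038738817,FALSE,FALSE,FALSE,NA
51,"minus",25,NA,1858.2614224921,FALSE,FALSE,FALSE,NA
52,"plus",27,"right",1890,FALSE,FALSE,FALSE,NA
53,"minus",26,NA,1906.27042429149,FALSE,FALSE,FALSE,NA
54,"minus",27,NA,1915.85059057549,FALSE,FALSE,FALSE,NA
55,"plus",28,"left",1930,FALSE,FALSE,FALSE,NA
56,"plus",29,"left",1978,TRUE,TRUE,TRUE,"left"
57,"plus",30,"right",2034,FALSE,FALSE,FALSE,NA
58,"minus",28,NA,2050.32399536297,FALSE,FALSE,FALSE,NA
59,"plus",31,"left",2082,FALSE,FALSE,FALSE,NA
60,"minus",29,NA,2112.81457895553,TRUE,FALSE,FALSE,"left"
61,"plus",32,"left",2122,FALSE,FALSE,FALSE,NA
62,"minus",30,NA,2161.70583740436,TRUE,FALSE,FALSE,"left"
63,"plus",33,"left",2190,FALSE,FALSE,FALSE,NA
64,"plus",34,"left",2298,FALSE,FALSE,FALSE,NA
65,"minus",31,NA,2396.14344010316,FALSE,FALSE,FALSE,NA
66,"plus",35,"right",2430,TRUE,FALSE,FALSE,"left"
67,"minus",32,NA,2463.87044234155,FALSE,FALSE,FALSE,NA
68,"plus",36,"right",2486,FALSE,FALSE,FALSE,NA
69,"minus",33,NA,2503.6660242416,FALSE,FALSE,FALSE,NA
70,"minus",34,NA,2509.31585678319,FALSE,FALSE,FALSE,NA
71,"plus",37,"left",2518,FALSE,FALSE,FALSE,NA
72,"minus",35,NA,2540.52626582235,FALSE,FALSE,FALSE,NA
73,"minus",36,NA,2551.37837534025,FALSE,FALSE,FALSE,NA
74,"minus",37,NA,2557.52246459574,FALSE,FALSE,FALSE,NA
75,"plus",38,"left",2566,FALSE,FALSE,FALSE,NA
76,"minus",38,NA,2603.99428043468,FALSE,FALSE,FALSE,NA
77,"plus",39,"right",2622,FALSE,FALSE,FALSE,NA
78,"plus",40,"right",2670,FALSE,FALSE,FALSE,NA
79,"minus",39,NA,2696.10911584692,FALSE,FALSE,FALSE,NA
80,"minus",40,NA,2705.40166322002,FALSE,FALSE,FALSE,NA
81,"plus",41,"right",2726,FALSE,FALSE,FALSE,NA
82,"plus",42,"left",2758,TRUE,TRUE,TRUE,"left"
83,"plus",43,"left",2838,FALSE,FALSE,FALSE,NA
84,"minus",41,NA,2909.95937320171,FALSE,FALSE,FALSE,NA
85,"minus",42,NA,2919.16525506647,TRUE,FALSE,FALSE,"left"
86,"plus",44,"right",2946,FALSE,FALSE,FALSE,NA
87,"plus",45,"right",2978,FALSE,FALSE,FALSE,NA
88,"minus",43,NA,3015.96931362897,TRUE,FALSE,FALSE,"left"
89,"plus",46,"right",3034,FALSE,FALSE,FALSE,NA
90,"minus",44,NA,3060.74241510639,FALSE,FALSE,FALSE,NA
91,"plus",47,"right",3074,FALSE,FALSE,FALSE,NA
92,"plus",48,"left",3122,FALSE,FALSE,FALSE,NA
93,"minus",45,NA,3139.67438791692,FALSE,FALSE,FALSE,NA
94,"minus",46,NA,3146.33776781242,FALSE,FALSE,FALSE,NA
95,"minus",47,NA,3153.96407674812,FALSE,FALSE,FALSE,NA
96,"minus",48,NA,3165.60739584547,FALSE,FALSE,FALSE,NA
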