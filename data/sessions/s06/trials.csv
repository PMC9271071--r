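"trial","cs_type","cs_index","side","cs_onset","approach","correct","drink","approach_side"
1,"plus",1,"right",30,TRUE,TRUE,TRUE,"right"
2,"plus",2,"left",70,TRUE,TRUE,TRUE,"left"
3,"plus",3,"left",138,TRUE,TRUE,TRUE,"left"
4,"minus",1,NA,208.050078220665,TRUE,FALSE,FALSE,"right"
5,"plus",4,"left",270,TRUE,TRUE,TRUE,"left"
6,"plus",5,"left",378,TRUE,TRUE,TRUE,"left"
7,"minus",2,NA,403.433558116667,TRUE,FALSE,FALSE,"right"
8,"minus",3,NA,412.788495317567,TRUE,FALSE,FALSE,"right"
9,"plus",6,"left",426,TRUE,TRUE,TRUE,"left"
10,"plus",7,"left",474,TRUE,TRUE,TRUE,"left"
11,"minus",4,NA,511.204299599864,TRUE,FALSE,FALSE,"left"
12,"plus",8,"left",522,TRUE,TRUE,TRUE,"left"
13,"plus",9,"right",570,TRUE,TRUE,TRUE,"right"
14,"plus",10,"right",602,TRUE,FALSE,FALSE,"left"
15,"minus",5,NA,618.892531437334,TRUE,FALSE,FALSE,"right"
16,"minus",6,NA,626.97931253491,FALSE,FALSE,FALSE,NA
17,"minus",7,NA,634.647366709542,TRUE,FALSE,FALSE,"left"
18,"plus",11,"right",642,TRUE,TRUE,TRUE,"right"
19,"plus",12,"left",750,TRUE,TRUE,TRUE,"left"
20,"plus",13,"left",882,TRUE,TRUE,TRUE,"left"
21,"minus",8,NA,905.465043852571,TRUE,FALSE,FALSE,"left"
22,"plus",14,"left",930,TRUE,TRUE,TRUE,"left"
23,"minus",9,NA,962.339416782372,TRUE,FALSE,FALSE,"left"
24,"minus",10,NA,969.913959686179,TRUE,FALSE,FALSE,"right"
25,"minus",11,NA,976.179760268889,TRUE,FALSE,FALSE,"left"
26,"plus",15,"left",986,TRUE,TRUE,TRUE,"left"
27,"plus",16,"left",1054,TRUE,FALSE,FALSE,"right"
28,"minus",12,NA,1083.40793958819,TRUE,FALSE,FALSE,"right"
29,"minus",13,NA,1097.19659176935,TRUE,FALSE,FALSE,"left"
30,"plus",17,"left",1122,TRUE,TRUE,TRUE,"left"
31,"minus",14,NA,1141.51185309095,TRUE,FALSE,FALSE,"left"
32,"minus",15,NA,1145.62143436307,FALSE,FALSE,FALSE,NA
33,"plus",18,"left",1154,TRUE,TRUE,TRUE,"left"
34,"minus",16,NA,1169.33133392921,TRUE,FALSE,FALSE,"right"
35,"minus",17,NA,1193.12486373307,TRUE,FALSE,FALSE,"right"
36,"plus",19,"left",1210,TRUE,TRUE,TRUE,"left"
37,"minus",18,NA,1233.255884354,TRUE,FALSE,FALSE,"left"
38,"plus",20,"right",1242,TRUE,TRUE,TRUE,"right"
39,"minus",19,NA,1301.57957675448,TRUE,FALSE,FALSE,"right"
40,"plus",21,"left",1310,TRUE,FALSE,FALSE,"right"
41,"minus",20,NA,1331.35463888897,TRUE,FALSE,FALSE,"left"
42,"minus",21,NA,1347.9401814295,TRUE,FALSE,FALSE,"right"
43,"plus",22,"left",1358,TRUE,TRUE,TRUE,"left"
44,"plus",23,"left",1398,TRUE,FALSE,FALSE,"right"
45,"minus",22,NA,1417.09350403724,TRUE,FALSE,FALSE,"left"
46,"minus",23,NA,1436.46635685675,TRUE,FALSE,FALSE,"left"
47,"minus",24,NA,1448.28494718019,FALSE,FALSE,FALSE,NA
48,"plus",24,"left",1466,TRUE,TRUE,TRUE,"left"
49,"minus",25,NA,1483.70055715227,TRUE,FALSE,FALSE,"left"
50,"plus",25,"left",1498,FALSE,FALSE,FALSE,NA
51,"plus",26,"right",1530,FALSE,FALSE,FALSE,NA
52,"minus",26,NA,1545.46825563582,TRUE,FALSE,FALSE,"left"
53,"minus",27,NA,1550.61936489353,FALSE,FALSE,FALSE,NA
54,"minus",28,NA,1554.85572933033,FALSE,FALSE,FALSE,NA
55,"plus",27,"left",1562,FALSE,FALSE,FALSE,NA
56,"minus",29,NA,1579.39797540568,FALSE,FALSE,FALSE,NA
57,"minus",30,NA,1592.33640091401,FALSE,FALSE,FALSE,NA
58,"plus",28,"right",1602,FALSE,FALSE,FALSE,NA
59,"minus",31,NA,1649.91346167121,FALSE,FALSE,FALSE,NA
60,"plus",29,"left",1670,TRUE,TRUE,TRUE,"left"
61,"plus",30,"left",1710,FALSE,FALSE,FALSE,NA
62,"minus",32,NA,1748.97291161725,TRUE,FALSE,FALSE,"right"
63,"plus",31,"left",1778,FALSE,FALSE,FALSE,NA
64,"plus",32,"right",1834,FALSE,FALSE,FALSE,NA
65,"plus",33,"left",1914,TRUE,TRUE,TRUE,"left"
66,"minus",33,NA,1956.0640729703,FALSE,FALSE,FALSE,NA
67,"plus",34,"left",2022,FALSE,FALSE,FALSE,NA
68,"minus",34,NA,2090.40863983333,FALSE,FALSE,FALSE,NA
69,"plus",35,"left",2130,FALSE,FALSE,FALSE,NA
70,"plus",36,"right",2210,TRUE,TRUE,TRUE,"right"
71,"plus",37,"left",2278,FALSE,FALSE,FALSE,NA
72,"plus",38,"right",2358,TRUE,TRUE,TRUE,"right"
73,"minus",35,NA,2385.57426276989,FALSE,FALSE,FALSE,NA
74,"plus",39,"left",2406,FALSE,FALSE,FALSE,NA
75,"plus",40,"right",2486,FALSE,FALSE,FALSE,NA
76,"minus",36,NA,2519.46561082546,FALSE,FALSE,FALSE,NA
77,"plus",41,"left",2554,TRUE,FALSE,FALSE,"right"
78,"minus",37,NA,2576.69623967819,FALSE,FALSE,FALSE,NA
79,"minus",38,NA,2580.82142383512,FALSE,FALSE,FALSE,NA
80,"minus",39,NA,2585.4505013586,FALSE,FALSE,FALSE,NA
81,"minus",40,NA,2590.67106566299,FALSE,FALSE,FALSE,NA
82,"minus",41,NA,2594.92867345223,FALSE,FALSE,FALSE,NA
83,"plus",42,"left",2602,FALSE,FALSE,FALSE,NA
84,"minus",42,NA,2638.96744445665,TRUE,FALSE,FALSE,"right"
85,"minus",43,NA,2644.22933996236,FALSE,FALSE,FALSE,NA
86,"plus",43,"left",2734,FALSE,FALSE,FALSE,NA
87,"plus",44,"left",2782,FALSE,FALSE,FALSE,NA
88,"plus",45,"right",2814,FALSE,FALSE,FALSE,NA
89,"minus",44,NA,2927.45099515747,FALSE,FALSE,FALSE,NA
90,"plus",46,"left",2946,TRUE,TRUE,TRUE,"left"
91,"minus",45,NA,2989.16975538945,FALSE,FALSE,FALSE,NA
92,"minus",46,NA,3004.32928000623,FALSE,FALSE,FALSE,NA
93,"plus",47,"left",3054,FALSE,FALSE,FALSE,NA
94,"minus",47,NA,3088.57368279481,TRUE,FALSE,FALSE,"left"
95,"minus",48,NA,3109.38979446003,TRUE,FALSE,FALSE,"left"
96,"plus",48,"left",3134,FALSE,FALSE,FALSE,NA
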