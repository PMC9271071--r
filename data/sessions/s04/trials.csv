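"trial","cs_type","cs_index","side","cs_onset","approach","correct","drink","approach_side"
1,"minus",1,NA,4.99125955626369,TRUE,FALSE,FALSE,"left"
2,"minus",2,NA,18.4211698248982,TRUE,FALSE,FALSE,"right"
3,"plus",1,"right",30,TRUE,TRUE,TRUE,"right"
4,"minus",3,NA,46.0680869249627,TRUE,FALSE,FALSE,"right"
5,"minus",4,NA,51.5847748373635,TRUE,FALSE,FALSE,"left"
6,"minus",5,NA,57.0926212165505,TRUE,FALSE,FALSE,"right"
7,"minus",6,NA,62.4115960453637,TRUE,FALSE,FALSE,"right"
8,"plus",2,"left",70,TRUE,TRUE,TRUE,"left"
9,"minus",7,NA,117.799002405256,TRUE,FALSE,FALSE,"right"
10,"plus",3,"right",150,TRUE,FALSE,FALSE,"left"
11,"minus",8,NA,176.815780706238,TRUE,FALSE,FALSE,"left"
12,"minus",9,NA,198.942253772169,FALSE,FALSE,FALSE,NA
13,"plus",4,"right",206,TRUE,TRUE,TRUE,"right"
14,"minus",10,NA,286.25795674976,TRUE,FALSE,FALSE,"right"
15,"plus",5,"right",314,TRUE,TRUE,TRUE,"right"
16,"minus",11,NA,363.936141883023,FALSE,FALSE,FALSE,NA
17,"plus",6,"right",394,TRUE,TRUE,TRUE,"right"
18,"minus",12,NA,409.279723527841,TRUE,FALSE,FALSE,"left"
19,"minus",13,NA,413.297202662565,TRUE,FALSE,FALSE,"right"
20,"minus",14,NA,418.415394942276,TRUE,FALSE,FALSE,"right"
21,"plus",7,"left",426,TRUE,TRUE,TRUE,"left"
22,"minus",15,NA,446.967139775399,TRUE,FALSE,FALSE,"left"
23,"minus",16,NA,460.404243676458,TRUE,FALSE,FALSE,"right"
24,"plus",8,"left",494,TRUE,TRUE,TRUE,"left"
25,"plus",9,"right",542,TRUE,TRUE,TRUE,"right"
26,"minus",17,NA,594.142238862347,TRUE,FALSE,FALSE,"right"
27,"plus",10,"left",622,TRUE,TRUE,TRUE,"left"
28,"plus",11,"left",678,TRUE,TRUE,TRUE,"left"
29,"minus",18,NA,695.303807898425,TRUE,FALSE,FALSE,"left"
30,"minus",19,NA,702.44534719782,TRUE,FALSE,FALSE,"right"
31,"plus",12,"left",734,TRUE,TRUE,TRUE,"left"
32,"minus",20,NA,763.889099968132,TRUE,FALSE,FALSE,"left"
33,"plus",13,"right",774,TRUE,TRUE,TRUE,"right"
34,"plus",14,"right",854,TRUE,TRUE,TRUE,"right"
35,"plus",15,"right",902,TRUE,TRUE,TRUE,"right"
36,"plus",16,"left",950,TRUE,TRUE,TRUE,"left"
37,"plus",17,"right",990,TRUE,TRUE,TRUE,"right"
38,"plus",18,"left",1098,TRUE,TRUE,TRUE,"left"
39,"minus",21,NA,1162.25296718953,TRUE,FALSE,FALSE,"right"
40,"plus",19,"left",1206,TRUE,TRUE,TRUE,"left"
41,"minus",22,NA,1223.2662725742,TRUE,FALSE,FALSE,"right"
42,"plus",20,"left",1338,TRUE,TRUE,FALSE,"left"
43,"minus",23,NA,1368.60009288276,TRUE,FALSE,FALSE,"right"
44,"plus",21,"left",1386,TRUE,TRUE,TRUE,"left"
45,"plus",22,"left",1494,TRUE,TRUE,TRUE,"left"
46,"plus",23,"left",1574,TRUE,TRUE,TRUE,"left"
47,"plus",24,"left",1614,TRUE,TRUE,TRUE,"left"
48,"minus",24,NA,1633.06645160727,TRUE,FALSE,FALSE,"right"
49,"minus",25,NA,1652.61713876994,TRUE,FALSE,FALSE,"right"
50,"plus",25,"right",1662,FALSE,FALSE,FALSE,NA
51,"plus",26,"left",1770,TRUE,FALSE,FALSE,"right"
52,"minus",26,NA,1805.13825655822,FALSE,FALSE,FALSE,NA
53,"plus",27,"left",1826,FALSE,FALSE,FALSE,NA
54,"plus",28,"right",1866,FALSE,FALSE,FALSE,NA
55,"plus",29,"right",1946,FALSE,FALSE,FALSE,NA
56,"minus",27,NA,1969.20244063623,FALSE,FALSE,FALSE,NA
57,"minus",28,NA,1974.60285377223,TRUE,FALSE,FALSE,"right"
58,"minus",29,NA,1978.68169686617,TRUE,FALSE,FALSE,"left"
59,"plus",30,"right",1986,FALSE,FALSE,FALSE,NA
60,"minus",30,NA,2004.99079812877,FALSE,FALSE,FALSE,NA
61,"minus",31,NA,2013.08656376647,FALSE,FALSE,FALSE,NA
62,"plus",31,"left",2026,TRUE,TRUE,TRUE,"left"
63,"minus",32,NA,2050.69633718487,FALSE,FALSE,FALSE,NA
64,"plus",32,"left",2158,FALSE,FALSE,FALSE,NA
65,"plus",33,"right",2266,FALSE,FALSE,FALSE,NA
66,"plus",34,"left",2322,FALSE,FALSE,FALSE,NA
67,"plus",35,"left",2430,TRUE,TRUE,TRUE,"left"
68,"minus",33,NA,2446.86558957212,FALSE,FALSE,FALSE,NA
69,"plus",36,"left",2462,FALSE,FALSE,FALSE,NA
70,"minus",34,NA,2483.29470742214,FALSE,FALSE,FALSE,NA
71,"plus",37,"right",2570,TRUE,TRUE,TRUE,"right"
72,"minus",35,NA,2590.33178780461,TRUE,FALSE,FALSE,"right"
73,"plus",38,"left",2610,FALSE,FALSE,FALSE,NA
74,"minus",36,NA,2631.97958304873,FALSE,FALSE,FALSE,NA
75,"plus",39,"left",2690,TRUE,TRUE,TRUE,"left"
76,"minus",37,NA,2715.13077244768,TRUE,FALSE,FALSE,"right"
77,"minus",38,NA,2720.28373395372,FALSE,FALSE,FALSE,NA
78,"minus",39,NA,2742.6363764191,FALSE,FALSE,FALSE,NA
79,"plus",40,"left",2758,TRUE,TRUE,TRUE,"left"
80,"minus",40,NA,2830.53961389838,FALSE,FALSE,FALSE,NA
81,"plus",41,"right",2838,FALSE,FALSE,FALSE,NA
82,"plus",42,"right",2918,TRUE,TRUE,TRUE,"right"
83,"minus",41,NA,2972.02922886424,FALSE,FALSE,FALSE,NA
84,"plus",43,"right",3026,TRUE,TRUE,TRUE,"right"
85,"minus",42,NA,3048.90712879272,FALSE,FALSE,FALSE,NA
86,"plus",44,"right",3158,TRUE,TRUE,TRUE,"right"
87,"plus",45,"right",3238,FALSE,FALSE,FALSE,NA
88,"plus",46,"right",3294,FALSE,FALSE,FALSE,NA
89,"minus",43,NA,3317.32856893772,FALSE,FALSE,FALSE,NA
90,"plus",47,"left",3326,FALSE,FALSE,FALSE,NA
91,"plus",48,"left",3358,FALSE,FALSE,FALSE,NA
92,"minus",44,NA,3382.42201298568,FALSE,FALSE,FALSE,NA
93,"minus",45,NA,3387.31163592916,TRUE,FALSE,FALSE,"right"
94,"minus",46,NA,3403.30717301648,FALSE,FALSE,FALSE,NA
95,"minus",47,NA,3407.46631633211,TRUE,FALSE,FALSE,"left"
96,"minus",48,NA,3414.72303690016,FALSE,FALSE,FALSE,NA
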