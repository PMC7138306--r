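id,speed_kmh,road_type,radius_m,diameter_cm,spacing_m,vehicle,observed_injury,cra_g,asi,grade_cra,grade_asi
1,81,straight,+inf,30,6,car,Moderate,65,1.75,II,II
2,67,straight,+inf,27,11,truck,Moderate,,1.21,,II
3,95,curve,3160,33,6,car,Fatal,102,2.41,IV,IV
4,60,curve,2300,11,3,car,Non,42,0.92,I,I
5,41,straight,+inf,32,7,car,Non,5,0.30,I,I
6,92,straight,+inf,35,8,car,Disabling,76,2.11,III,III
7,65,curve,780,30,4,car,Moderate,58,1.32,I,II
8,76,curve,2340,24,5,car,Moderate,72,1.66,II,II
9,87,curve,1540,25,8,car,Disabling,86,2.04,III,III
10,93,curve,2340,18,9,car,Disabling,92,2.18,III,III
11,104,curve,4560,22,10,car,Fatal,110,2.62,IV,IV
12,114,curve,1260,28,12,car,Fatal,122,2.99,IV,IV
13,67,curve,3410,34,4,car,Moderate,64,1.44,II,II
14,89,curve,560,15,3,car,Disabling,84,1.99,III,III
15,76,curve,270,30,5,car,Moderate,66,1.63,II,II
16,56,curve,1890,26,8,car,Minor,44,0.97,I,I
17,81,curve,690,25,5,car,Disabling,77,1.82,III,III
18,69,curve,1560,27,7,car,Moderate,62,1.43,II,II
19,79,curve,3570,33,5,car,Disabling,80,1.85,III,III
20,78,curve,2560,20,5,car,Moderate,73,1.69,II,II
21,83,curve,780,17,6,car,Disabling,75,1.79,III,III
22,81,curve,980,14,8,car,Moderate,71,1.68,II,II
23,64,curve,1320,10,7,car,Minor,45,1.02,I,II
24,61,curve,2460,11,7,car,Non,43,0.95,I,I
25,53,curve,5270,18,5,car,Non,38,0.80,I,I
26,77,curve,670,30,4,car,Disabling,74,1.73,III,II
27,89,curve,780,32,6,car,Disabling,90,2.16,III,III
28,78,curve,730,33,10,car,Moderate,72,1.75,II,II
29,74,curve,650,35,9,car,Moderate,67,1.62,II,II
30,68,curve,1780,25,8,car,Moderate,62,1.38,II,II
31,69,curve,1250,26,4,car,Moderate,63,1.43,II,II
32,85,curve,1200,22,6,car,Disabling,82,1.94,III,III
33,90,curve,500,24,2,car,Disabling,90,2.14,III,III
34,97,curve,610,20,7,car,Fatal,101,2.30,IV,IV
35,99,straight,+inf,36,9,car,Fatal,103,2.34,IV,IV
36,67,straight,+inf,12,8,car,Fatal,32,0.99,I,I
37,56,straight,+inf,15,11,car,Non,8,0.58,I,I
38,101,straight,+inf,40,5,car,Fatal,99,2.54,IV,IV
39,69,straight,+inf,9,8,car,Disabling,32,0.99,I,I
40,55,straight,+inf,18,9,car,Non,15,0.64,I,I
41,49,straight,+inf,17,4,car,Non,22,0.55,I,I
42,89,straight,+inf,23,3,car,Disabling,85,2.04,III,III
43,97,straight,+inf,25,8,car,Disabling,80,2.21,III,III
44,83,straight,+inf,26,8,car,Moderate,61,1.73,II,II
45,47,straight,+inf,29,7,car,Non,14,0.52,I,I
46,88,straight,+inf,33,10,car,Fatal,63,1.91,II,III
47,86,straight,+inf,32,5,truck,Disabling,,1.98,,III
48,75,straight,+inf,33,4,truck,Disabling,,1.63,,III
49,70,curve,560,31,6,truck,Moderate,,1.45,,II
50,68,curve,1230,27,7,truck,Moderate,,1.37,,II
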