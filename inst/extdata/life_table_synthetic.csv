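age,qx
0,4.55348132589739e-05
1,4.9922657906154e-05
2,5.47333142956186e-05
3,6.00075221357521e-05
4,6.57899461069533e-05
5,7.21295539082289e-05
6,7.90800306976758e-05
7,8.67002334258293e-05
8,9.50546888982551e-05
9,0.000104214139769021
10,0.000114256143072256
11,0.000125265726338641
12,0.000137336106827313
13,0.000150569479933083
14,0.000165077883407472
15,0.000180984144667717
16,0.000198422919160723
17,0.000217541828510637
18,0.000238502708008848
19,0.000261482973914373
20,0.00028667712203212
21,0.000314298370117538
22,0.000344580457854127
23,0.000377779619444296
24,0.000414176745279549
25,0.000454079750705771
26,0.000497826171596438
27,0.000545786008294802
28,0.00059836484150555
29,0.000656007245919077
30,0.000719200529745612
31,0.000788478830955119
32,0.000864427603858076
33,0.000947688532756286
34,0.00103896491275635
35,0.00113902754148276
36,0.00124872116939123
37,0.00136897156066373
38,0.00150079322131225
39,0.00164529785612222
40,0.00180370362147819
41,0.00197734524692683
42,0.00216768510458754
43,0.0023763253122171
44,0.0026050209628955
45,0.00285569458192925
46,0.00313045191966621
47,0.0034315991974766
48,0.00376166193316263
49,0.00412340548147516
50,0.00451985743520056
51,0.00495433204234996
52,0.00543045680525378
53,0.00595220143768238
54,0.00652390936633152
55,0.0071503319728724
56,0.00783666578201692
57,0.00858859280929491
58,0.00941232428905636
59,0.0103146480080187
60,0.0113029794717956
61,0.012385417130421
62,0.0135708018828877
63,0.0148687810689135
64,0.0162898771370126
65,0.0178455611497007
66,0.0195483312471277
67,0.0214117961370623
68,0.0234507636089273
69,0.0256813339789419
70,0.0281209982582132
71,0.0307887406910051
72,0.0337051451308295
73,0.0368925045010663
74,0.0403749323172946
75,0.0441784749222737
76,0.0483312226925501
77,0.0528634180081385
78,0.057807557223117
79,0.0631984832242991
80,0.0690734644063594
81,0.0754722550143309
82,0.0824371307990538
83,0.090012892791184
84,0.098246830722052
85,0.107188636208407
86,0.116890254285061
87,0.127405660239078
88,0.138790547012343
89,0.15110190675869
90,0.164397488557786
91,0.17873511292633
92,0.194171822796299
93,0.210762850270281
94,0.228560378994604
95,0.247612083758224
96,0.267959432344961
97,0.289635740223365
98,0.312663976895321
99,0.337054334220135
100,0.362801582358936
101,0.389882258648363
102,0.418251759051865
103,0.447841430894914
104,0.478555798944985
105,0.510270093452838
106,0.542828286523609
107,0.576041878978589
108,0.609689709188288
109,0.643519072226217
110,0.677248434747308
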