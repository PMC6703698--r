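segment_id,name,parent_id,angle_1d,length_mm,mean_diameter_mm,proximal_diameter_mm,distal_diameter_mm,distensibility_1e3_mmHg,region
1,Aorta ascendens 1,,90,18,68,68.18,67.39,6.85,
2,A coronaria sinistra,1,180,20,19,23.638,12.10,3.17,heart
3,A coronaria dextra,1,0,20,19,23.638,12.10,3.17,heart
4,Aorta ascendens 2,1,90,64,67,67.22,66.82,6.80,
5,Truncus brachiocephalicus 1,4,160,38,39,38.882,38.88,4.90,
6,A subclavia sinistra 1,5,155,39,26,25.332,25.33,3.79,
7,Truncus costocervicalis sinister,6,90,10,11,12.102,10.50,2.34,muscle
8,A subclavia sinistra 2,6,155,19,24,24.11,24.11,3.68,
9,A cervicalis profunda sinistra,8,115,70,3,2.82,2.82,0.87,muscle
10,A subclavia sinistra 3,8,155,14,24,24.11,24.11,3.68,
11,A vertebralis sinistra,10,135,95,12,14.17,9.98,2.45,brain
12,A subclavia sinistra 4,10,240,40,23,22.89,22.89,3.57,
13,A thoracica interna sinistra,12,280,137,12,12.11,12.11,2.44,other
14,A subclavia sinistra 5,12,240,7,23,22.89,22.89,3.57,
15,A cervicalis superficialis sinistra,14,180,80,8,10.31,4.79,1.90,muscle
16,A axillaris sinistra 1,14,310,62,21,21.50,20.37,3.38,
17,A suprascapularis sinistra,16,70,15,6,7.68,3.52,1.59,muscle
18,A axillaris sinistra 2,16,310,58,20,19.90,19.90,3.28,
19,A subscapularis sinistra,18,10,10,17,16.80,16.80,2.96,muscle
20,A axillaris sinistra 3,18,310,23,18,18.02,18.02,3.09,
21,A circumflexa humeri cranialis sinistra,20,230,30,5,6.11,2.79,1.39,muscle
22,A axillaris sinistra 4,20,270,70,17,17.05,17.05,2.99,
23,A profunda brachii sinistra,22,325,5,11,11.281,9.60,2.23,muscle
24,A axillaris sinistra 5,22,270,82,14,15.35,12.79,2.67,
25,A collateralis ulnaris sinistra,24,320,5,6,8.60,4.92,1.75,muscle
26,A mediana sinistra,24,270,145,7,10.01,5.30,1.90,muscle
27,Truncus brachiocephalicus 2,5,160,50,39,38.88,38.88,4.90,
28,Truncus costocervicalis dexter,27,90,10,11,14.38,7.07,2.34,muscle
29,Truncus brachiocephalicus 3,27,160,10,39,38.88,38.88,4.90,
30,A cervicalis profunda dextra,29,115,70,3,2.81,2.81,0.87,muscle
31,Truncus brachiocephalicus 4,29,160,10,39,38.88,38.88,4.90,
32,A vertebralis dextra,31,135,95,12,16.95,7.12,2.54,brain
33,Truncus brachiocephalicus 5,31,160,20,26,26.96,25.00,4.24,
34,A subclavia dextra 1,33,240,30,26,25.00,25.00,3.76,
35,A thoracica interna dextra,34,280,137,11,12.12,12.10,2.44,other
36,A cervicalis superficialis dextra,34,180,80,3,8.07,8.02,1.90,muscle
37,A axillaris dextra 1,34,310,62,21,20.95,20.94,3.38,
38,A suprascapularis,37,70,15,6,6.43,5.47,1.59,muscle
39,A axillaris dextra 2,37,310,58,20,19.90,19.90,3.28,
40,A subscapularis dextra,39,10,10,17,16.80,16.80,2.96,muscle
41,A axillaris dextra 3,39,310,23,18,18.02,18.02,3.09,
42,A circumflexa humeri cranialis dextra,41,230,30,5,6.115,2.79,1.39,muscle
43,A axillaris dextra 4,41,270,70,17,17.05,17.05,2.99,
44,A profunda brachii dextra,43,325,5,11,10.47,10.47,2.23,muscle
45,A axillaris dextra 5,43,270,82,14,17.05,10.42,2.67,
46,A collateralis ulnaris dextra,45,320,5,6,8.60,4.92,1.75,muscle
47,A mediana dextra,45,270,145,7,10.00,5.30,1.90,muscle
48,Truncus bicaroticus,31,165,78,22,22.06,21.26,3.45,
49,A carotis communis sinistra,48,110,710,12,13.45,10.35,2.42,
50,A carotis interna sinistra,49,90,120,4,4.43,3.53,1.25,brain
51,A occipitalis sinistra,49,60,45,5,4.94,4.13,1.35,brain
52,A carotis externa sinistra 1,49,130,65,10,10.04,10.04,2.18,
53,Truncus linguofacialis sinister,52,180,80,6,6.54,5.50,1.60,brain
54,A carotis externa sinistra 2,52,90,41,9,9.22,8.83,2.04,
55,Ramus massetericus sinister,54,255,20,2,2.51,1.21,0.82,brain
56,A carotis externa sinistra 3,54,90,13,9,8.56,8.55,1.98,
57,A auricularis caudalis sinistra,56,55,10,3,3.953,1.74,1.07,brain
58,A carotis externa sinistra 4,56,90,23,7,8.56,5.15,1.76,
59,A temporalis superficialis sinistra,58,60,20,2,3.44,2.48,1.05,brain
58b,A carotis externa sinistra 5,58,90,5,5,5.15,5.15,1.46,brain
60,A carotis communis dextra,48,110,710,12,13.45,10.35,2.42,
61,A carotis interna dextra,60,90,120,4,4.43,3.53,1.25,brain
62,A occipitalis dextra,60,60,45,5,4.94,4.13,1.35,brain
63,A carotis externa dextra 1,60,130,65,10,10.04,10.04,2.18,
64,Truncus linguofacialis dexter,63,180,80,6,6.54,5.50,1.60,brain
65,A carotis externa dextra 2,63,90,41,9,9.22,8.83,2.04,
66,Ramus massetericus dexter,65,255,20,2,2.51,1.21,0.82,brain
67,A carotis externa dextra 3,65,90,13,9,8.56,8.55,1.98,
68,A aurocularis caudalis dextra,67,55,10,3,3.95,1.74,1.07,brain
69,A carotis externa dextra 4,67,90,23,7,8.56,5.15,1.76,
70,A temporalis superficialis dextra,69,60,20,2,3.44,2.48,1.05,brain
69b,A carotis externa dextra 5,69,90,5,5,5.15,5.15,1.46,brain
71,Arcus aortae (lig. Art Botalli),4,45,77,54,58.07,49.53,5.97,
72,Aorta descendens 1,71,45,105,45,48.21,40.62,5.32,
73,A broncho-oesophagea,72,270,66,11,13.71,6.31,2.26,other
74,Aorta descendens 2,72,0,486,36,38.44,32.28,4.64,
75,A coeliaca,74,270,20,15,19.31,9.24,2.78,splanchnic
76,Aorta descendens 3,74,0,48,29,28.70,28.70,4.09,
77,A mesenterica cranialis,76,270,20,11,13.48,7.56,2.29,splanchnic
78,Aorta descendens 4,76,0,30,29,28.70,28.70,4.09,
79,A renalis dextra,78,270,30,11,13.26,7.21,2.26,kidney
80,Aorta descendens 5,78,0,20,29,28.70,28.70,4.09,
81,A renalis sinistra,80,270,30,11,13.26,7.21,2.26,kidney
82,Aorta descendens 6,80,0,104,29,28.70,28.70,4.09,
83,A ovarica sinistra,82,270,300,3,2.76,2.76,1.00,other
84,A ovarica dextra,82,270,300,3,2.76,2.76,1.00,other
85,Aorta descendens 7,82,0,40,29,28.70,28.70,4.09,
86,A mesenterica caudalis,85,270,10,8,9.78,4.63,1.85,splanchnic
87,Aorta descendens 8,85,0,63,29,28.70,28.70,4.09,
88,A iliaca interna sinistra,87,330,30,18,20.19,15.12,0.92,other
89,A iliaca externa sinistra 1,87,315,30,17,16.93,16.24,0.88,
90,A circumflexa iliumprofunda sinistra,89,240,160,6,7.58,3.66,0.48,muscle
91,A iliaca externa sinistra 2,89,280,29,16,15.99,15.54,0.86,
92,A uterina sinistra,91,260,200,3,3.19,3.19,0.33,other
93,A iliaca externa sinistra 3,91,280,230,15,15.30,15.30,0.84,
94,A profunda femoris sinistra,93,335,30,8,7.93,7.23,0.55,muscle
95,A femoralis sinistra 1,93,280,51,15,15.26,14.27,0.82,
96,A circumflexa femoris lateralis sinistra,95,240,30,6,7.69,3.62,0.48,muscle
97,A femoralis sinistra 2,95,280,180,11,10.78,10.78,0.68,
98,A saphena sinistra,97,285,625,3,2.59,2.59,0.29,muscle
99,A femoralis sinistra 3,97,280,25,10,10.78,9.71,0.66,
100,A genus descendens sinistra,99,260,25,3,4.46,3.47,0.38,muscle
99b,A femoralis sinistra 4,99,280,5,10,9.71,9.71,0.64,muscle
101,A iliaca interna dextra,87,330,30,18,20.19,15.12,0.92,other
102,A iliaca externa dextra 1,87,315,30,17,16.98,16.19,0.88,
103,A uterina dextra,102,260,200,6,3.19,3.19,0.33,other
104,A iliaca externa dextra 2,102,280,29,16,15.97,15.56,0.86,
105,A circumflexa iliumprofunda dextra,104,240,160,3,7.52,3.77,0.48,muscle
106,A iliaca externa dextra 3,104,280,230,15,15.30,15.30,0.84,
107,A profunda femoris dextra,106,335,30,8,7.93,7.23,0.55,muscle
108,A femoralis dextra 1,106,280,51,15,15.26,14.27,0.82,
109,A circumflexa femoris lateralis dextra,108,240,30,6,7.69,3.62,0.48,muscle
110,A femoralis dextra 2,108,280,180,11,10.78,10.78,0.68,
111,A saphena dextra,110,285,625,3,2.59,2.59,0.29,muscle
112,A femoralis dextra 3,110,280,25,10,10.78,9.71,0.66,
113,A genus descendens dextra,112,260,25,3,4.46,3.47,0.38,muscle
112b,A femoralis dextra 4,112,280,5,9.71,9.71,9.71,0.64,muscle
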