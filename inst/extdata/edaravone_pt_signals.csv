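rank,soc,pt,a,ror,ror_lo,ror_hi,prr,prr_lo,prr_hi,chisq,ic,ic025
1,General disorders and administration site conditions,death,589,8.64,7.93,9.42,7.74,7.16,8.37,3504.11,2.95,2.83
2,General disorders and administration site conditions,disease progression,266,28.26,24.97,31.99,26.8,23.83,30.14,6591.96,4.74,4.56
3,General disorders and administration site conditions,drug ineffective,252,2.16,1.9,2.45,2.1,1.87,2.36,148.98,1.07,0.89
4,General disorders and administration site conditions,fatigue,139,2.07,1.75,2.45,2.04,1.74,2.39,74.34,1.03,0.78
5,General disorders and administration site conditions,condition aggravated,133,4.94,4.15,5.86,4.83,4.05,5.76,405.81,2.27,2.02
6,General disorders and administration site conditions,asthenia,122,4.17,3.49,5,4.1,3.44,4.89,286.96,2.03,1.78
7,General disorders and administration site conditions,therapeutic response unexpected,98,27.68,22.66,33.83,27.16,22.33,33.04,2460.23,4.76,4.47
8,General disorders and administration site conditions,gait disturbance,92,5.95,4.84,7.31,5.85,4.81,7.12,371.11,2.55,2.25
9,General disorders and administration site conditions,no adverse event,34,2.19,1.56,3.06,2.18,1.56,3.04,21.73,1.12,0.64
10,General disorders and administration site conditions,gait inability,23,5.72,3.8,8.61,5.7,3.78,8.6,89.03,2.51,1.93
11,General disorders and administration site conditions,adverse event,22,3.12,2.05,4.74,3.11,2.06,4.69,31.46,1.63,1.04
12,General disorders and administration site conditions,general physical health deterioration,20,2.11,1.36,3.27,2.1,1.36,3.23,11.6,1.07,0.45
13,General disorders and administration site conditions,energy increased,17,38.44,23.85,61.98,38.32,23.94,61.34,614.17,5.25,4.58
14,General disorders and administration site conditions,adverse drug reaction,17,2.09,1.3,3.37,2.09,1.31,3.35,9.66,1.06,0.39
15,General disorders and administration site conditions,catheter site swelling,5,69.18,28.64,167.07,69.11,28.61,166.95,332.02,6.1,4.93
16,General disorders and administration site conditions,catheter site pain,5,24.67,10.25,59.39,24.64,10.2,59.52,112.99,4.62,3.46
17,General disorders and administration site conditions,infusion site extravasation,5,8.04,3.34,19.32,8.03,3.32,19.4,30.73,3,1.85
18,General disorders and administration site conditions,catheter site thrombosis,5,165.74,68.18,402.93,165.58,68.54,400,797.16,7.33,6.16
19,General disorders and administration site conditions,infusion site pain,4,3.49,1.31,9.29,3.48,1.31,9.27,7.08,1.8,0.53
20,General disorders and administration site conditions,secretion discharge,4,3.6,1.35,9.59,3.6,1.35,9.59,7.49,1.85,0.58
21,General disorders and administration site conditions,loss of control of legs,3,13.1,4.22,40.68,13.09,4.2,40.8,33.44,3.71,2.29
22,Nervous system disorders,amyotrophic lateral sclerosis,182,1497.86,1272.05,1763.76,1442.88,1233.48,1687.83,213743.11,10.2,9.97
23,Nervous system disorders,aphasia,81,35.55,28.53,44.31,34.99,28.2,43.41,2661.09,5.12,4.81
24,Nervous system disorders,speech disorder,73,18.52,14.69,23.34,18.26,14.43,23.1,1188.52,4.19,3.86
25,Nervous system disorders,cerebral infarction,42,23.35,17.23,31.66,23.16,17.26,31.08,887.74,4.53,4.09
26,Nervous system disorders,balance disorder,21,3.08,2.01,4.73,3.07,1.99,4.73,29.42,1.62,1.02
27,Nervous system disorders,cerebral haemorrhage,15,5.53,3.33,9.19,5.52,3.32,9.19,55.48,2.46,1.75
28,Nervous system disorders,dysarthria,14,5.22,3.09,8.82,5.21,3.07,8.84,47.59,2.38,1.65
29,Nervous system disorders,muscle contractions involuntary,10,41.86,22.46,78,41.78,22.31,78.23,395.41,5.38,4.52
30,Nervous system disorders,dysstasia,9,3.85,2,7.41,3.85,2.02,7.35,18.96,1.94,1.05
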