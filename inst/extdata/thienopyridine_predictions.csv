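compound_id,experimental_pic50,comfa_predicted,comsia_predicted,subset
1,4.89,4.81,4.92,train
2,5.56,4.81,5.07,test
3,5.88,5.09,5.34,test
4,5.60,5.63,5.62,train
5,4.86,4.93,4.83,train
6,5.32,5.40,5.19,train
7,5.69,5.68,5.44,train
8,5.65,5.66,5.57,train
9,4.96,5.26,5.07,test
10,5.95,5.01,5.11,test
11,4.77,4.88,4.72,train
12,5.69,4.95,4.93,test
13,5.22,5.20,5.18,train
14,5.13,5.09,5.04,train
15,5.07,5.05,5.02,train
16,4.85,4.80,5.00,train
17,5.88,5.85,5.99,train
18,5.18,5.22,5.36,train
19,5.29,5.34,5.48,train
20,5.23,5.16,5.20,train
21,5.53,4.85,5.50,test
22,5.61,5.73,5.77,train
23,5.60,5.70,5.69,train
24,5.61,5.66,5.58,train
25,6.12,6.07,5.99,train
26,6.16,6.00,6.28,train
27,6.24,6.24,5.98,train
28,6.55,6.54,6.28,train
29,6.92,6.99,6.80,train
30,6.16,6.17,6.02,train
31,7.38,7.20,7.25,train
32,6.92,7.00,7.01,train
33,6.16,6.06,6.33,train
34,6.28,6.66,6.32,test
35,5.69,5.60,6.07,train
36,5.88,5.49,6.00,test
37,6.82,5.65,6.39,test
38,5.10,5.59,5.92,test
39,7.00,7.04,6.94,train
40,5.83,5.87,5.83,train
41,5.70,5.64,5.72,train
42,6.22,6.15,6.52,train
43,6.30,6.28,6.10,train
44,7.14,6.88,6.96,test
45,6.20,6.26,6.15,train
46,6.85,6.89,6.82,train
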