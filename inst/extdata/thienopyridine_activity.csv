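compound_id,ic50_uM,subset
1,12.7,train
2,2.7,test
3,1.3,test
4,2.5,train
5,13.5,train
6,4.7,train
7,2.0,train
8,2.2,train
9,10.8,test
10,1.1,test
11,16.9,train
12,2.0,test
13,6.0,train
14,7.41,train
15,8.50,train
16,14.0,train
17,1.30,train
18,6.60,train
19,5.10,train
20,5.80,train
21,2.90,test
22,2.41,train
23,2.52,train
24,2.41,train
25,0.75,train
26,0.68,train
27,0.57,train
28,0.28,train
29,0.12,train
30,0.68,train
31,0.04,train
32,0.12,train
33,0.68,train
34,0.52,test
35,2.01,train
36,1.32,test
37,0.15,test
38,7.81,test
39,0.098,train
40,1.45,train
41,1.95,train
42,0.59,train
43,0.50,train
44,0.07,test
45,0.63,train
46,0.14,train
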