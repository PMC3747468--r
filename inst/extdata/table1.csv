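no,bp,id,prr,p,pha,tw,mts_fe,mts_ann,trf_fe,trf_ann
1,0,3.80,0.40,2.60,5.00,0.10,464.49,464.71,39.93,39.99
2,0,4.23,0.55,2.95,8.75,0.15,416.30,415.05,38.40,38.59
3,0,4.65,0.70,3.30,12.50,0.20,399.83,392.63,35.56,35.75
4,0,5.08,0.85,3.65,16.25,0.25,377.19,382.49,31.37,31.26
5,0,5.50,1.00,4.00,20.00,0.30,380.56,377.39,26.36,26.48
6,9,3.80,0.55,3.30,16.25,0.30,452.25,457.14,38.37,38.38
7,9,4.23,0.70,3.65,20.00,0.10,415.59,419.10,36.48,36.57
8,9,4.65,0.85,4.00,5.00,0.15,404.94,405.94,33.66,33.72
9,9,5.08,1.00,2.60,8.75,0.20,432.04,427.96,33.96,33.82
10,9,5.50,0.40,2.95,12.50,0.25,393.19,404.48,35.67,35.54
11,18,3.80,0.70,4.00,8.75,0.25,468.89,468.30,36.74,36.80
12,18,4.23,0.85,2.60,12.50,0.30,576.54,574.13,37.94,37.90
13,18,4.65,1.00,2.95,16.25,0.10,444.50,437.91,35.72,35.71
14,18,5.08,0.40,3.30,20.00,0.15,429.80,416.79,36.65,36.33
15,18,5.50,0.55,3.65,5.00,0.20,391.64,397.72,33.37,33.49
16,27,3.80,0.85,2.95,20.00,0.20,608.56,617.34,37.47,37.15
17,27,4.23,1.00,3.30,5.00,0.25,532.07,529.34,36.37,36.23
18,27,4.65,0.40,3.65,8.75,0.30,491.02,481.84,36.73,36.58
19,27,5.08,0.55,4.00,12.50,0.10,460.59,463.83,34.67,34.41
20,27,5.50,0.70,2.60,16.25,0.15,463.35,469.46,35.14,35.44
21,36,3.80,1.00,3.65,12.50,0.15,919.85,918.26,35.19,35.31
22,36,4.23,0.40,4.00,16.25,0.20,787.66,789.04,34.90,35.05
23,36,4.65,0.55,2.60,20.00,0.25,770.40,765.61,36.66,36.90
24,36,5.08,0.70,2.95,5.00,0.30,605.92,611.19,35.97,36.01
25,36,5.50,0.85,3.30,8.75,0.10,527.13,526.30,33.54,33.46
26,25.4,4.7,0.748,3.1,9.53,0.255,488.62,483.69,36.59,36.41
27,0.5,5.093,0.885,3.59,5.68,0.183,375.29,380.79,31.47,31.64
28,31.05,5.144,0.624,3.947,18.07,0.11,504.19,510.02,34.01,33.62
29,16.87,4.3,0.774,3.507,8.95,0.156,444.71,436.37,36.46,36.73
30,25.02,5.46,0.546,3.347,6.58,0.3,429.47,427.33,34.48,34.43
31,10.24,3.87,0.577,3.135,9.515,0.28,447.07,465.53,38.51,38.73
32,6.696,4.79,0.448,3.241,18.58,0.152,412.10,401.96,37.189,37.16
33,23.25,4.39,0.463,2.86,6.16,0.187,495.95,506.34,38.365,38.56
34,21.55,5.334,0.745,2.943,17.91,0.115,420.82,424.14,34.036,34.89
35,31.64,5.49,0.543,3.528,14.39,0.294,476.86,472.29,34.167,33.80
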