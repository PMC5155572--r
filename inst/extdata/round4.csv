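# round_id: round4
# divisor: 8
label,dose_Pi,dose_Pa,dose_EH,dose_Ci,dose_Ge,dose_Mi,surv_Biu87,surv_J-82,surv_EJ,surv_5637,surv_T24,surv_UM-UC-3,surv_H-bc,accs_printed,acs_printed
1,40,160,250,1500,0,1000,1.06,1.09,10.47,12.67,6.71,4.66,0.08,4.21,4.59
2,8,6.4,250,12,0,200,13.15,16.03,33.23,,,,,20.80,
3,8,0,50,60,1,200,10.83,24.08,44.31,,,,,26.41,
4,40,1.28,50,300,0.2,1000,3.44,3.20,20.32,49.82,6.07,19.97,69.34,8.99,21.52
5,0,160,250,1500,0,1000,1.76,1.55,13.79,31.48,6.53,11.74,1.83,5.70,8.58
6,0,1.28,50,60,0,8,67.33,81.67,95.23,,,,,81.41,
7,1.6,0,50,1500,5,8,2.49,10.85,49.72,58.46,67.09,39.16,79.74,21.02,38.44
8,0,0,50,60,5,8,19.33,83.10,89.61,,,,,64.01,
9,0,0,250,1500,0.2,8,4.74,11.47,48.27,54.30,60.35,35.24,73.68,21.49,36.01
10,40,160,0,1500,5,0,2.33,9.01,39.92,54.91,64.83,25.80,72.95,17.09,33.72
11,1.6,160,2,300,0.04,8,19.08,46.99,65.19,,,,,43.75,
12,1.6,0,2,1500,1,0,3.03,17.53,59.73,,,,,26.76,
13,1.6,6.4,2,1500,1,40,3.98,13.42,51.97,,,,,23.12,
14,1.6,0,2,0,0.2,200,11.15,22.31,42.01,,,,,25.16,
15,1.6,0,50,0,5,8,16.07,83.37,86.61,,,,,62.02,
16,8,6.4,2,60,0.2,1000,4.11,5.41,23.16,58.89,14.88,19.74,76.52,10.89,25.34
17,8,6.4,50,60,5,200,4.84,15.91,37.99,63.70,32.74,31.35,77.57,19.58,33.01
18,0.32,32,50,300,0.2,0,32.59,55.90,73.87,,,,,54.12,
19,8,160,0,1500,5,0,2.01,11.47,49.02,59.90,62.31,34.55,69.74,20.83,36.13
20,8,0,0,300,0.2,1000,2.97,3.26,18.98,58.19,11.91,44.89,72.60,8.40,26.60
21,0,32,2,300,5,0,11.37,69.36,77.62,,,,,52.78,
22,40,0,50,12,0,200,13.41,21.93,36.29,,,,,23.88,
23,8,160,0,0,0.2,200,13.91,24.21,36.91,,,,,25.01,
24,40,0,250,300,5,40,5.62,25.25,44.56,,,,,25.14,
25,40,0,250,60,0,0,19.78,65.75,66.58,,,,,50.70,
26,0,32,50,0,5,1000,2.76,8.46,25.51,55.04,8.76,11.12,72.55,12.25,23.03
27,0,0,10,1500,1,0,4.77,20.82,63.19,,,,,29.60,
28,40,0,50,0,1,200,12.09,28.68,37.58,,,,,26.11,
29,40,160,50,300,5,200,5.70,19.46,39.91,,,,,21.69,
30,40,32,0,12,0,1000,6.88,9.93,20.74,55.21,10.50,22.07,73.72,12.51,24.88
31,0,160,10,1500,0.2,0,2.83,15.54,40.61,56.03,63.41,36.00,73.03,19.66,35.93
32,0,6.4,0,1500,1,1000,1.70,2.21,15.55,41.74,4.91,20.91,35.05,6.49,15.26
33,0,0,10,0,5,1000,2.42,9.93,26.85,67.91,8.76,12.29,81.70,13.06,26.23
34,8,0,50,1500,0.2,1000,1.41,1.86,16.89,38.98,6.51,27.58,36.08,6.72,16.16
35,8,0,0,1500,5,40,2.23,12.82,47.02,72.15,56.17,22.86,78.21,20.69,36.43
36,1.6,160,2,0,0.2,1000,3.39,8.68,21.00,53.50,8.21,18.08,75.08,11.02,23.49
37,40,0,50,1500,5,1000,1.73,1.71,13.66,47.58,5.96,25.76,15.01,5.70,13.93
38,0,32,250,1500,0.2,1000,2.01,1.61,15.55,48.65,5.54,21.01,3.23,6.39,12.20
39,8,0,50,1500,5,40,3.74,12.36,48.61,74.74,58.66,25.44,76.61,21.57,37.52
40,0.32,0,250,1500,0,200,2.17,7.14,28.13,39.77,5.62,21.67,4.30,12.48,13.60
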