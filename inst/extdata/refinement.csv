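# round_id: refinement
# divisor: 5
label,dose_Pi,dose_Pa,dose_EH,dose_Ci,dose_Ge,dose_Mi,surv_Biu87,surv_EJ,surv_H-bc,surv_T24,surv_UM-UC-3,acs_printed
1,0,0,0,1500,0,1000,4.50,17.00,29.50,3.60,3.00,11.52
2,0,0,250,1500,0,1000,2.00,15.40,4.79,1.60,2.90,5.34
3,0,160,0,1500,0,1000,1.30,10.40,19.82,3.70,3.00,7.64
4,40,0,0,1500,0,1000,3.50,16.70,5.84,1.60,3.60,6.25
5,0,0,0,1500,5,1000,5.70,20.00,7.57,4.80,3.50,8.31
6,0,0,50,1500,0,1000,4.30,22.40,5.11,3.20,2.70,7.54
7,0,32,0,1500,0,1000,1.90,14.30,42.68,3.90,3.00,13.16
8,8,0,0,1500,0,1000,1.70,20.00,8.50,3.80,3.60,7.52
9,0,0,0,1500,1,1000,3.50,19.40,29.95,4.50,3.10,12.09
10,0,0,0,1500,0,200,5.30,27.70,41.03,5.60,4.60,16.85
11,0,0,250,1500,0,200,0.60,16.70,12.43,6.50,3.60,7.97
12,0,160,0,1500,0,200,1.90,25.10,13.56,1.60,4.20,9.27
13,40,0,0,1500,0,200,2.80,22.50,17.24,3.50,4.10,10.03
14,0,0,0,1500,5,200,3.70,25.70,32.23,8.90,4.10,14.93
15,0,0,0,300,0,1000,13.40,30.90,57.10,7.09,32.00,28.10
16,0,0,250,300,0,1000,9.90,29.80,29.70,29.50,14.10,22.60
17,0,160,0,300,0,1000,10.70,23.50,44.00,7.69,19.40,21.06
18,0,0,0,300,5,1000,13.30,31.80,49.90,12.76,25.50,26.65
19,0,0,0,300,0,200,6.80,27.00,50.30,71.70,34.60,38.08
20,0,0,250,300,0,200,36.40,52.80,73.20,8.87,64.50,47.15
21,0,160,0,300,0,200,21.70,40.90,48.40,45.97,30.10,37.41
22,40,0,0,300,0,200,27.20,38.70,55.90,55.81,32.30,41.98
23,0,0,0,300,5,200,30.70,55.90,49.90,46.27,22.10,40.97
24,40,32,0,300,0,200,8.40,39.30,64.20,50.98,49.60,42.50
25,40,0,50,300,0,200,30.40,38.10,55.00,40.97,37.10,40.31
26,40,0,0,300,1,200,29.30,47.80,58.30,34.88,30.90,40.24
27,8,0,0,300,5,200,24.20,48.40,70.90,46.03,43.40,46.59
28,0,32,0,300,5,200,14.90,46.50,63.00,51.52,58.70,46.92
29,0,0,50,300,5,200,12.50,37.50,63.10,47.05,41.10,40.25
30,0,32,250,300,0,200,14.50,44.90,58.60,53.67,49.70,44.27
31,8,0,250,300,0,200,28.10,40.50,47.80,33.09,19.70,33.84
32,0,0,250,300,1,200,27.30,45.10,33.10,31.25,17.10,30.77
33,0,0,250,300,5,200,22.70,49.90,45.40,39.53,22.40,35.99
34,40,32,50,1500,5,200,13.20,40.40,51.90,33.27,21.20,31.99
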