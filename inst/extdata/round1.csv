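# round_id: round1
# divisor: 6
label,dose_Pi,dose_Pa,dose_EH,dose_Ci,dose_Ge,dose_Mi,surv_5637,surv_H-bc,surv_J-82,surv_T24,surv_EJ,surv_Biu87,acs_printed
1,1.6,32,10,300,5,8,24.58,52.57,43.69,36.41,46.55,21.67,37.58
2,8,6.4,2,300,1,8,43.82,56.01,55.27,44.71,51.31,49.15,50.04
3,8,32,50,300,0.04,8,45.43,52.30,50.62,45.20,40.41,51.10,47.51
4,1.6,1.28,10,12,5,8,65.40,59.60,72.90,62.06,69.10,26.78,59.31
5,8,32,50,60,5,40,42.03,58.01,46.08,39.05,41.61,31.50,43.05
6,0.32,160,10,1500,0.2,1000,1.23,18.96,6.07,7.97,30.67,7.64,12.09
7,40,1.28,50,60,0.2,200,26.47,48.40,23.75,32.91,37.67,48.37,36.26
8,0.32,6.4,250,1500,1,1000,0.51,3.40,6.62,11.67,21.79,16.09,10.01
9,0.32,6.4,10,300,0.2,1000,11.57,42.60,11.53,20.07,35.01,20.32,23.52
10,8,160,10,12,0.2,200,16.17,51.76,26.82,29.74,36.40,37.65,33.09
11,1.6,1.28,50,60,0.04,8,62.93,57.78,65.16,61.60,56.02,72.26,62.63
12,8,160,50,1500,5,40,13.59,26.84,13.40,14.80,36.62,8.56,18.97
13,40,1.28,250,300,5,40,26.19,30.01,18.67,17.25,22.28,17.59,22.00
14,40,1.28,250,60,0.04,8,47.21,33.02,31.00,24.05,28.35,33.22,32.81
15,0.32,1.28,10,1500,1,40,30.10,33.64,24.30,22.03,45.20,14.02,28.21
16,40,1.28,50,12,1,200,25.27,44.03,24.77,34.08,34.79,45.38,34.72
17,40,32,50,1500,5,200,6.62,15.80,7.63,11.21,31.27,12.87,14.23
18,8,6.4,50,1500,5,8,23.94,29.12,16.23,15.78,37.86,14.05,22.83
19,1.6,6.4,250,1500,0.2,200,1.99,5.48,8.26,8.73,23.63,13.30,10.23
20,8,1.28,2,300,0.04,40,48.26,58.13,56.80,39.38,53.67,65.93,53.70
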