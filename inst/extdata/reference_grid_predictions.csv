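age,sex,mrs,median,q25,q75,ed,nonelective_days,elective_days
65,female,1,15.92,9.41,19.60,8.84,25.20,2.73
65,female,3,9.17,4.44,11.33,8.93,27.32,1.45
65,female,5,1.25,0.54,1.40,1.54,11.03,1.06
65,male,1,15.01,8.55,18.46,7.90,23.00,2.75
65,male,3,8.47,3.78,10.32,7.84,25.00,1.45
65,male,5,1.05,0.44,1.28,1.26,8.15,0.99
75,female,1,9.51,4.91,11.88,6.04,23.55,2.26
75,female,3,4.67,1.97,5.57,5.35,24.68,0.97
75,female,5,0.80,0.33,1.28,1.12,9.84,0.81
75,male,1,8.83,4.29,10.93,5.33,21.26,2.27
75,male,3,4.21,1.60,4.91,4.62,22.21,0.95
75,male,5,0.67,0.28,1.15,0.91,6.91,0.74
85,female,1,5.14,2.36,6.27,3.81,21.29,1.72
85,female,3,2.31,1.06,2.57,3.14,21.88,0.58
85,female,5,0.53,0.22,1.05,0.84,8.86,0.61
85,male,1,4.70,1.99,5.61,3.32,18.89,1.71
85,male,3,2.05,0.86,2.25,2.67,19.28,0.56
85,male,5,0.46,0.19,0.92,0.69,6.11,0.58
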