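mrs,sex,s1,s3,s5,s10,median_le
0,female,0.98,0.91,0.83,0.58,11.37
0,male,0.97,0.90,0.81,0.54,10.68
1,female,0.95,0.87,0.79,0.52,10.24
1,male,0.93,0.85,0.76,0.47,9.53
2,female,0.95,0.84,0.71,0.29,7.70
2,male,0.93,0.81,0.67,0.23,7.15
3,female,0.87,0.71,0.51,0.00,5.12
3,male,0.84,0.66,0.46,0.00,4.64
4,female,0.69,0.52,0.31,0.00,3.16
4,male,0.63,0.45,0.25,0.00,2.52
5,female,0.44,0.06,0.00,0.00,0.85
5,male,0.38,0.02,0.00,0.00,0.71
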