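patient,session,stage,n_marks,tre_mean,tre_sd,tre_max
1,1,rigid,4,5.16,1.16,6.56
1,2,rigid,4,9.17,5.46,16.72
1,3,rigid,4,6.43,2.65,10.24
1,1,elastic,4,2.42,0.73,3.35
1,2,elastic,4,4.18,2.17,7.28
1,3,elastic,4,4.11,2.17,7.20
2,1,rigid,6,3.2,1.60,5.26
2,2,rigid,6,4.2,2.19,6.42
2,3,rigid,4,4.4,4.13,10.39
2,1,elastic,6,3.46,0.92,4.67
2,2,elastic,6,3.02,1.26,4.96
2,3,elastic,4,4.29,3.58,9.63
3,1,rigid,5,6.41,2.68,10.17
3,2,rigid,4,2.93,0.90,4.27
3,3,rigid,4,4.44,1.66,6.81
3,1,elastic,5,5.51,2.44,8.51
3,2,elastic,4,2.81,1.06,4.09
3,3,elastic,4,4.2,1.45,6.15
4,1,rigid,5,5.39,2.51,8.33
4,2,rigid,5,7.95,2.62,11.13
4,3,rigid,4,9.86,5.34,14.46
4,1,elastic,5,3.82,2.89,8.76
4,2,elastic,5,4.83,3.73,11.22
4,3,elastic,4,5.1,2.87,8.35
5,1,rigid,5,3.08,1.13,4.57
5,2,rigid,4,2.87,1.38,3.83
5,3,rigid,2,2.99,1.64,4.15
5,1,elastic,5,3.16,0.94,4.55
5,2,elastic,4,2.14,1.00,3.63
5,3,elastic,2,2.52,2.13,4.02
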