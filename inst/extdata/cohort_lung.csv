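patient,session,stage,lung,ve_percent,ce_mm,jac
1,1,rigid,right,-8.07,3.10,0.89
1,2,rigid,right,11.30,3.98,0.84
1,3,rigid,right,-8.54,4.73,0.87
1,1,elastic,right,-0.69,0.77,0.95
1,2,elastic,right,0.62,1.22,0.95
1,3,elastic,right,-0.19,0.53,0.95
2,1,rigid,right,4.44,1.43,0.90
2,2,rigid,right,10.12,2.71,0.87
2,3,rigid,right,-2.17,2.82,0.71
2,1,elastic,right,2.03,0.53,0.93
2,2,elastic,right,4.78,0.78,0.93
2,3,elastic,right,1.61,0.32,0.93
3,1,rigid,right,3.33,2.89,0.88
3,2,rigid,right,3.73,1.77,0.88
3,3,rigid,right,-3.73,1.77,0.91
3,1,elastic,right,2.09,0.28,0.95
3,2,elastic,right,1.59,0.33,0.95
3,3,elastic,right,-0.41,0.39,0.96
4,1,rigid,right,-0.55,0.95,0.90
4,2,rigid,right,-1.44,1.30,0.89
4,3,rigid,right,-11.14,1.56,0.82
4,1,elastic,right,0.48,0.18,0.93
4,2,elastic,right,-1.15,0.28,0.94
4,3,elastic,right,-3.11,0.88,0.93
5,1,rigid,right,7.64,3.01,0.89
5,2,rigid,right,0.90,2.68,0.91
5,3,rigid,right,-16.16,6.12,0.80
5,1,elastic,right,3.45,0.73,0.94
5,2,elastic,right,-0.72,0.50,0.96
5,3,elastic,right,-5.23,5.46,0.87
1,1,rigid,left,24.85,7.35,0.72
1,2,rigid,left,-17.87,9.76,0.76
1,3,rigid,left,45.14,7.86,0.54
1,1,elastic,left,1.97,0.40,0.95
1,2,elastic,left,-0.81,0.14,0.96
1,3,elastic,left,3.10,0.84,0.92
2,1,rigid,left,-5.14,1.22,0.90
2,2,rigid,left,-5.55,2.05,0.89
2,3,rigid,left,2.64,0.93,0.89
2,1,elastic,left,0.25,0.39,0.94
2,2,elastic,left,1.49,0.26,0.95
2,3,elastic,left,1.11,0.76,0.92
3,1,rigid,left,-1.97,2.15,0.80
3,2,rigid,left,-4.53,2.58,0.87
3,3,rigid,left,-17.38,5.15,0.81
3,1,elastic,left,1.99,1.94,0.89
3,2,elastic,left,0.01,2.11,0.90
3,3,elastic,left,-6.82,3.23,0.88
4,1,rigid,left,-0.80,2.00,0.91
4,2,rigid,left,-5.42,2.14,0.90
4,3,rigid,left,-10.69,4.06,0.84
4,1,elastic,left,0.80,0.06,0.95
4,2,elastic,left,-0.59,0.37,0.96
4,3,elastic,left,-2.08,0.56,0.95
5,1,rigid,left,2.35,0.89,0.92
5,2,rigid,left,4.60,0.96,0.93
5,3,rigid,left,4.26,0.99,0.90
5,1,elastic,left,2.23,0.16,0.95
5,2,elastic,left,0.49,0.09,0.96
5,3,elastic,left,2.05,1.52,0.94
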