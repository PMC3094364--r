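patient,session,stage,cc
1,1,rigid,0.92
1,2,rigid,0.91
1,3,rigid,0.88
2,1,rigid,0.97
2,2,rigid,0.97
2,3,rigid,0.96
3,1,rigid,0.90
3,2,rigid,0.96
3,3,rigid,0.90
4,1,rigid,0.92
4,2,rigid,0.92
4,3,rigid,0.86
5,1,rigid,0.95
5,2,rigid,0.96
5,3,rigid,0.94
1,1,elastic,0.98
1,2,elastic,0.98
1,3,elastic,0.98
2,1,elastic,0.99
2,2,elastic,0.99
2,3,elastic,0.98
3,1,elastic,0.98
3,2,elastic,0.98
3,3,elastic,0.97
4,1,elastic,0.98
4,2,elastic,0.97
4,3,elastic,0.97
5,1,elastic,0.98
5,2,elastic,0.98
5,3,elastic,0.97
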