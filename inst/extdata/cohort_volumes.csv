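patient,session,lung,quantity,volume_cm3
1,1,left,kvct,632.39
1,1,left,rigid_mvct,475.22
1,1,left,elastic_mvct,619.95
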