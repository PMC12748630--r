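score,control,patient
0,0,0
1,0,1
2,6,4
3,26,27
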