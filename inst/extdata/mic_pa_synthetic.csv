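"mic","frequency"
0.25,0.002
0.5,0.006
1,0.042
2,0.19
4,0.45
8,0.2
16,0.06
32,0.05
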