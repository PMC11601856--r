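lower,upper,monthly_rate
0,0.05,0
0.05,0.25,0.02
0.25,0.5,0.05
0.5,1,0.1
1,2,0.2
2,Inf,0.4
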