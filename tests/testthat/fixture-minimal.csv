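time,B_right,t_LEFT
0.000,0.1,1.5
0.001,0.2,-2.5
0.002,0.3,3.5
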