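hu,rsp
-1000,0.001
0,1.0
1000,1.55
3000,2.40
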