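hu,spr
-1024,0.001
-750,0.25
-120,0.90
-20,0.98
0,1.00
60,1.04
120,1.08
600,1.30
1000,1.52
1500,1.60
3072,2.20
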