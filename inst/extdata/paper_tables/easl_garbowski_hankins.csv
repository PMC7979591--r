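"","0","1","2","3"
"0",246,0,0,0
"1",34,68,0,0
"2",0,14,19,0
"3",0,0,4,1
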