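"","no","yes"
"no",246,6
"yes",0,134
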