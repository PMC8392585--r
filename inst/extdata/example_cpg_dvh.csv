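dose,volume
0,50
40,50
70,0
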