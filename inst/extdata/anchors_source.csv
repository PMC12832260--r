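item_id,a,b,c
a1,0.8,-1,0
a2,1,0,0
a3,1.2,1,0
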