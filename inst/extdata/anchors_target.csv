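item_id,a,b,c
a1,0.4,-1,0
a2,0.5,1,0
a3,0.6,3,0
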