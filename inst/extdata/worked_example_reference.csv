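id,c1,c2,x
a,0,0,10
b,1,0,10
c,0,1,10
d,1,1,10
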