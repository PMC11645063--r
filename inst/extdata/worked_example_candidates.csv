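id,c1,c2,x_hat
q1,0.5,0.5,10.5
q2,0.5,0.5,11.5
q3,0.5,0.5,12.5
q4,0.5,0.5,13.5
q5,0.5,0.5,14.5
q6,0.5,0.5,15.5
q7,0.5,0.5,16.5
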