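# Linear chain decay: X1 -> X2 -> X3
species X1 X2 X3
init 10000 1 0
T 5
k r1 : 1 X1 -> 1 X2 ; c=1
k r2 : 1 X2 -> 1 X3 ; c=1
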