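# Linear pure-birth (Yule) order-study system
species X
init 1000
T 12
k birth : 1 X -> 2 X ; c=0.2
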