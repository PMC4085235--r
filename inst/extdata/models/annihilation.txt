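# Non-linear pairwise annihilation order-study system
species X Y
init 10000 10000
T 12
k annihilate : 1 X + 1 Y -> 0 ; c=1e-5
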