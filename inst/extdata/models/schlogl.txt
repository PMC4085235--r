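# Schlogl bimodal system; A and B buffered
species X A B
init 250 100000 200000
fixed A B
T 10
k r1 : 1 A + 2 X -> 3 X ; c=3e-7
k r2 : 3 X -> 1 A + 2 X ; c=1e-4
k r3 : 1 B -> 1 X ; c=1e-3
k r4 : 1 X -> 1 B ; c=3.5
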