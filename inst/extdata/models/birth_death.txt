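# Immigration-death toy with Poisson(5) stationary law
species X
init 0
T 10
k in : 0 -> 1 X ; c=5
k out : 1 X -> 0 ; c=1
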