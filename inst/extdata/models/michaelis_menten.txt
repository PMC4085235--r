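# Michaelis-Menten enzyme kinetics (X2 = enzyme, X4 = product)
species X1 X2 X3 X4
init 1000 200 2000 0
T 10
k bind : 1 X1 + 1 X2 -> 1 X3 ; c=1e-4
k unbind : 1 X3 -> 1 X1 + 1 X2 ; c=0.5
k cat : 1 X3 -> 1 X2 + 1 X4 ; c=0.5
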