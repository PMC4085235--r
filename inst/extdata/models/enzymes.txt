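# Mutually inhibiting enzymes: 8 species, 12 reactions
species A B EA EB EAB EAB2 EBA EBA2
init 20000 15000 9500 9500 2000 500 2000 500
T 2
k prodA : 1 EA -> 1 EA + 1 A ; c=15
k prodB : 1 EB -> 1 EB + 1 B ; c=15
k inhA1 : 1 EA + 1 B <-> 1 EAB ; c=5e-4, 2
k inhA2 : 1 EAB + 1 B <-> 1 EAB2 ; c=1e-3, 6
k degA : 1 A -> 0 ; c=5
k inhB1 : 1 EB + 1 A <-> 1 EBA ; c=5e-4, 2
k inhB2 : 1 EBA + 1 A <-> 1 EBA2 ; c=1e-3, 6
k degB : 1 B -> 0 ; c=5
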