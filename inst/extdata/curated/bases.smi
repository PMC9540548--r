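CC(C)(C)O[Na]
O=C(O[Cs])O[Cs]
O=P(O[K])(O[K])O[K]
O=C(O[K])O[K]
C1CCC2=NCCCN2CC1
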