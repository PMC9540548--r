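CC(=O)O[Pd]OC(=O)C
Cl[Pd]Cl
CS(=O)(=O)O[Pd]OS(C)(=O)=O
Cl[Pd](Cl)(P(c1ccccc1)(c1ccccc1)c1ccccc1)P(c1ccccc1)(c1ccccc1)c1ccccc1
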