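Delftia
Acinetobacter
Pseudomonas
Sphingomonas
Janthinobacterium
Duganella
Paenibacillus
Micrococcus
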