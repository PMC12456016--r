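Ralstonia
Delftia
Pseudomonas
Sphingomonas
Methylobacterium
Bosea
Ochrobactrum
Brevundimonas
Chryseobacterium
Flavobacterium
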