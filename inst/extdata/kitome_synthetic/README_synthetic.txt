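Synthetic genus lists. These are NOT the seven published reagent-contaminant
("kitome") lists; they are constructed fixtures with the same shape (one
genus per line, one list per file) for exercising the concordance
statistics. Genus names are drawn from taxa commonly discussed as reagent
contaminants or low-biomass residents.
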