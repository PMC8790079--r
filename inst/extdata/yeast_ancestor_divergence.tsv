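# Published counts of mutated proteins whose sequence already differed
# between the laboratory ancestor and the reference genome, per yeast
# data set (Sc1, Sc2), with the total number of proteins carrying
# variants in each.
dataset	n_mutated_proteins	n_ancestor_divergent
Sc1	961	126
Sc2	754	16
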