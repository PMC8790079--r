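# Published per-ancestor bookkeeping for a Chlamydomonas reinhardtii
# mutation-accumulation panel: unique mutated proteins per ancestral
# background, how many of those proteins already carried variants in the
# ancestor relative to the reference genome, MA lines per background, and
# protein variants submitted for scoring.
ancestor_id	n_mutated_proteins	n_prior_variant_proteins	n_lines	n_protein_variants
CC1373	381	234	12	390
CC1952	80	75	14	82
CC2342	188	171	12	192
CC2344	239	225	15	244
CC2931	351	322	14	358
CC2937	130	109	15	131
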