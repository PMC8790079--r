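# Published cluster/supporting-sequence diagnostics: per data set, the
# number of proteins analyzed, how many were scored from fewer than 30
# clusters, and how many had fewer than 50 supporting sequences.
dataset	n_proteins	n_few_clusters	n_few_support
yeast	1534	122	79
cr	1444	187	1082
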