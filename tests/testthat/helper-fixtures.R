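## Programmatic fixtures shared across tests.

## A minimal score-table row in the shape score_variants() emits.
score_row <- function(line_id, gene_id, score,
                      protein_id = paste0(gene_id, ".t1"),
                      variant = "A2V", threshold = -2.5,
                      n_clusters = 30L, n_supporting = 50L) {
  data.frame(line_id = line_id, gene_id = gene_id,
             transcript_id = protein_id, protein_id = protein_id,
             variant = variant, score = score,
             classification = ifelse(is.na(score), NA_character_,
                                     ifelse(score < threshold, "deleterious",
                                            "neutral")),
             n_clusters = n_clusters, n_supporting = n_supporting,
             flags = "", stringsAsFactors = FALSE)
}

score_rows <- function(line_id, scores, gene_prefix = "g") {
  if (length(scores) == 0L) return(score_row(line_id, "g0", 0)[0, ])
  do.call(rbind, lapply(seq_along(scores), function(i)
    score_row(line_id, paste0(gene_prefix, i), scores[i])))
}

## Expand a per-ancestor bookkeeping table (columns ancestor_id,
## n_mutated_proteins, n_prior_variant_proteins, n_lines,
## n_protein_variants) into record-level data whose aggregation must
## reproduce the table exactly.
expand_bookkeeping <- function(counts) {
  recs <- list(); anc_map <- character()
  for (i in seq_len(nrow(counts))) {
    a <- as.character(counts$ancestor_id[i])
    P <- counts$n_mutated_proteins[i]
    Q <- counts$n_prior_variant_proteins[i]
    L <- counts$n_lines[i]
    V <- counts$n_protein_variants[i]
    stopifnot(V >= P, Q <= P)
    lines <- sprintf("%s_L%02d", a, seq_len(L))
    anc_map[lines] <- a
    prot <- sprintf("%s_p%04d", a, seq_len(P))
    first <- data.frame(line_id = lines[(seq_len(P) - 1L) %% L + 1L],
                        protein_id = prot,
                        ancestral_divergent = seq_len(P) <= Q,
                        stringsAsFactors = FALSE)
    extra_n <- V - P
    extra <- if (extra_n > 0L)
      data.frame(line_id = lines[seq_len(extra_n) %% L + 1L],
                 protein_id = prot[(seq_len(extra_n) - 1L) %% P + 1L],
                 ancestral_divergent = seq_len(extra_n) <= Q,
                 stringsAsFactors = FALSE)
    else NULL
    recs[[a]] <- rbind(first, extra)
  }
  list(records = do.call(rbind, recs), line_ancestors = anc_map)
}

## A deterministic two-exon plus-strand gene model:
##   CDS "ATGGCTTGGAAATGA" -> protein "MAWK"
demo_gene_model <- function(strand = "+") {
  cds <- "ATGGCTTGGAAATGA"
  genomic <- paste0(substr(cds, 1, 6), "GTACAG", substring(cds, 7))
  if (strand == "+")
    gene_model("gX", "gX.t1", "+", c(1, 13), c(6, 21), genomic)
  else {
    L <- nchar(genomic)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(genomic)))
    gene_model("gX", "gX.t1", "-", L - c(21, 6) + 1, L - c(13, 1) + 1, rc)
  }
}

## Small cached synthetic study reused by several test files.
cached_study <- local({
  store <- new.env()
  function(seed = 101, ...) {
    key <- paste0("s", seed, paste(c(...), collapse = "_"))
    if (is.null(store[[key]]))
      store[[key]] <- suppressWarnings(suppressMessages(
        simulate_ma_study(sim_config(seed = seed, ...))))
    store[[key]]
  }
})
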