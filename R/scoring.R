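#' Scoring configuration
#'
#' Parameters of the delta-alignment scorer. Defaults follow the
#' published PROVEAN procedure: BLOSUM62 substitution matrix,
#' semi-global affine-gap alignment with gap open 10 and gap extend 1
#' (a gap of length L costs `gap_open + L * gap_extend`), supporting
#' sequences clustered at 75% identity, the top 30 clusters most
#' similar to the query scored, and a deleterious threshold of -2.5.
#'
#' @param substitution_matrix Named integer matrix over the 20 amino
#'   acids; default is BLOSUM62 (from Biostrings).
#' @param gap_open,gap_extend Positive gap penalties,
#'   `gap_extend <= gap_open`.
#' @param cluster_identity Identity fraction for greedy clustering, in
#'   (0, 1].
#' @param max_clusters Number of top clusters scored.
#' @param threshold Classification cutoff: scores strictly below it are
#'   deleterious.
#' @param min_clusters_flag,min_support_flag Diagnostic limits below
#'   which the `few_clusters` / `few_support` flags are raised.
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(substitution_matrix = NULL, gap_open = 10,
                           gap_extend = 1, cluster_identity = 0.75,
                           max_clusters = 30L, threshold = -2.5,
                           min_clusters_flag = 30L, min_support_flag = 50L) {
  if (is.null(substitution_matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    substitution_matrix <- e$BLOSUM62
  }
  stopifnot(gap_open > 0, gap_extend > 0, gap_extend <= gap_open,
            cluster_identity > 0, cluster_identity <= 1, max_clusters >= 1)
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 cluster_identity = cluster_identity,
                 max_clusters = as.integer(max_clusters),
                 threshold = threshold,
                 min_clusters_flag = as.integer(min_clusters_flag),
                 min_support_flag = as.integer(min_support_flag)),
            class = "scoring_config")
}

AA_OK_RE <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

check_protein <- function(x, what) {
  if (!nzchar(x)) stop(what, " sequence is empty")
  if (!grepl(AA_OK_RE, x))
    stop("unknown residue(s) in ", what, " sequence: ",
         gsub("[ACDEFGHIKLMNPQRSTVWY]", "", x))
  invisible(TRUE)
}

#' Semi-global alignment score of two protein sequences
#'
#' Optimal affine-gap alignment score with free terminal gaps
#' (overlap alignment), the flavor used to compare query and mutant
#' proteins against supporting sequences. Symmetric in its arguments.
#'
#' @param a,b Protein sequences.
#' @param config A [scoring_config()].
#' @return Numeric alignment score.
#' @export
align_score <- function(a, b, config = scoring_config()) {
  check_protein(a, "first"); check_protein(b, "second")
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "overlap",
    substitutionMatrix = config$substitution_matrix,
    gapOpening = config$gap_open, gapExtension = config$gap_extend,
    scoreOnly = TRUE)
}

## Vectorized: score of `seq` against each supporting sequence.
align_scores_many <- function(seq, support, config) {
  check_protein(seq, "query/mutant")
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(support), Biostrings::AAString(seq),
    type = "overlap", substitutionMatrix = config$substitution_matrix,
    gapOpening = config$gap_open, gapExtension = config$gap_extend,
    scoreOnly = TRUE)
}

#' Percent identity of two sequences
#'
#' Identity is matches divided by alignment columns (gaps count as
#' columns) of the global affine-gap alignment under the configured
#' scoring scheme.
#'
#' @inheritParams align_score
#' @return Identity fraction in \[0, 1\].
#' @export
percent_identity <- function(a, b, config = scoring_config()) {
  identity_many(a, b, config)
}

## Vectorized identity of several sequences against one (one batched
## alignment call: the S4 dispatch overhead dominates at desk scale).
identity_many <- function(seqs, b, config) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(seqs), Biostrings::AAString(b), type = "global",
    substitutionMatrix = config$substitution_matrix,
    gapOpening = config$gap_open, gapExtension = config$gap_extend)
  m <- Biostrings::nmatch(aln)
  x <- Biostrings::nmismatch(aln)
  ## alignment columns = residues of both sequences minus aligned pairs
  ncol <- nchar(seqs) + nchar(b) - m - x
  m / ncol
}

#' Greedy clustering of supporting sequences
#'
#' CD-HIT-style greedy clustering: sequences are sorted by decreasing
#' length (ties keep input order) and each joins the first existing
#' cluster whose representative (founding, longest member) shares at
#' least `cluster_identity` identity with it; otherwise it founds a new
#' cluster.
#'
#' @param sequences Character vector of protein sequences.
#' @param config A [scoring_config()].
#' @return List of integer vectors of indices into `sequences`
#'   (a partition).
#' @export
greedy_cluster <- function(sequences, config = scoring_config()) {
  stopifnot(length(sequences) >= 1L)
  ord <- order(-nchar(sequences))   # stable: ties keep input order
  clusters <- list()
  reps <- character()
  for (i in ord) {
    k <- 0L
    if (length(reps)) {
      hits <- which(identity_many(reps, sequences[i], config) >=
                    config$cluster_identity)
      if (length(hits)) k <- hits[1L]
    }
    if (k > 0L) clusters[[k]] <- c(clusters[[k]], i)
    else {
      clusters[[length(clusters) + 1L]] <- i
      reps[length(clusters)] <- sequences[i]
    }
  }
  clusters
}

#' Select the clusters most similar to the query
#'
#' Ranks clusters by their representative's percent identity to the
#' query (descending), breaking ties by longer representative and then
#' input order, and keeps the first `max_clusters`.
#'
#' @param clusters Partition from [greedy_cluster()].
#' @param sequences The supporting sequences the partition indexes.
#' @param query Query protein.
#' @param config A [scoring_config()].
#' @return The selected clusters, ranked.
#' @export
select_top_clusters <- function(clusters, sequences, query,
                                config = scoring_config()) {
  stopifnot(length(clusters) >= 1L)
  reps <- vapply(clusters, function(cl) sequences[cl[1L]], character(1))
  ident <- identity_many(reps, query, config)
  ord <- order(-ident, -nchar(reps), seq_along(clusters))
  clusters[ord][seq_len(min(config$max_clusters, length(clusters)))]
}

#' Build a supporting set object
#'
#' Clusters the supporting sequences and selects the top clusters for
#' a query, caching the per-cluster mean alignment scores of the query
#' so that many variants of one protein can be scored cheaply.
#'
#' @param query Query protein sequence.
#' @param sequences Supporting protein sequences.
#' @param config A [scoring_config()].
#' @return A list of class `supporting_set`.
#' @export
supporting_set <- function(query, sequences, config = scoring_config()) {
  sequences <- toupper(sequences)
  clusters <- greedy_cluster(sequences, config)
  selected <- select_top_clusters(clusters, sequences, query, config)
  sel_seqs <- sequences[unlist(selected)]
  sel_index <- rep(seq_along(selected), lengths(selected))
  query_scores <- align_scores_many(query, sel_seqs, config)
  query_means <- as.numeric(tapply(query_scores, sel_index, mean))
  structure(list(query = toupper(query), sequences = sequences,
                 clusters = clusters, selected = selected,
                 sel_seqs = sel_seqs, sel_index = sel_index,
                 query_means = query_means,
                 n_clusters = length(clusters),
                 n_supporting = length(sequences)),
            class = "supporting_set")
}

score_flags <- function(n_clusters, n_supporting, unscored, config) {
  f <- character()
  if (unscored) f <- "unscored"
  if (n_clusters < config$min_clusters_flag) f <- c(f, "few_clusters")
  if (n_supporting < config$min_support_flag) f <- c(f, "few_support")
  paste(f, collapse = ",")
}

score_result_row <- function(protein_id, description, score, config,
                             n_clusters, n_supporting) {
  unscored <- is.na(score)
  data.frame(
    protein_id = protein_id, variant = description, score = score,
    classification = if (unscored) NA_character_ else
      if (score < config$threshold) "deleterious" else "neutral",
    n_clusters = n_clusters, n_supporting = n_supporting,
    flags = score_flags(n_clusters, n_supporting, unscored, config),
    stringsAsFactors = FALSE)
}

#' Delta alignment score of a protein variant
#'
#' The score is the mean, over the selected clusters, of the
#' within-cluster mean alignment score of the mutant minus that of the
#' query. A variant is classified deleterious when its score falls
#' strictly below the configured threshold. An empty supporting set, an
#' empty mutant sequence, or a mutant whose alignment cannot be formed
#' yields an unscored result (flag `unscored`, `score` `NA`) rather
#' than a number.
#'
#' @param query Query protein, or a [supporting_set()] built from it.
#' @param variant A variant description (see [parse_variant()]) or a
#'   mutant protein sequence.
#' @param support Supporting sequences (character vector), ignored when
#'   `query` is already a `supporting_set`.
#' @param config A [scoring_config()].
#' @param protein_id Identifier for the result row.
#' @return One-row data frame: `protein_id`, `variant`, `score`,
#'   `classification`, `n_clusters`, `n_supporting`, `flags`.
#' @export
delta_score <- function(query, variant, support = NULL,
                        config = scoring_config(),
                        protein_id = NA_character_) {
  ss <- if (inherits(query, "supporting_set")) query
        else {
          if (is.null(support) || length(support) == 0L)
            return(score_result_row(protein_id, variant, NA_real_, config, 0L, 0L))
          supporting_set(query, support, config)
        }
  qseq <- ss$query
  ## a description always contains a position digit; a raw sequence never does
  if (grepl("[0-9]", variant)) {
    description <- variant
    mutant <- parse_variant(variant, qseq)$mutant_seq
  } else {
    description <- "<sequence>"
    mutant <- toupper(variant)
  }

  if (!nzchar(mutant) || !grepl(AA_OK_RE, mutant))
    return(score_result_row(protein_id, description, NA_real_, config,
                            ss$n_clusters, ss$n_supporting))
  score <- tryCatch({
    mut_scores <- align_scores_many(mutant, ss$sel_seqs, config)
    mut_means <- as.numeric(tapply(mut_scores, ss$sel_index, mean))
    mean(mut_means - ss$query_means)
  }, error = function(e) NA_real_)
  score_result_row(protein_id, description, score, config,
                   ss$n_clusters, ss$n_supporting)
}

#' Score a table of protein variants
#'
#' Applies [delta_score()] to every nonsynonymous variant record
#' emitted by [mutate_study()], reusing one [supporting_set()] per
#' protein. Synonymous records are dropped (they are not protein
#' variants); mutant sequences that cannot be aligned are kept with the
#' `unscored` flag.
#'
#' @param variants Data frame from [mutate_study()] (`$variants`).
#' @param queries Named character vector of query proteins by
#'   `protein_id`.
#' @param support Named list of supporting-sequence character vectors
#'   by `protein_id`.
#' @param config A [scoring_config()].
#' @return Data frame of score results with `line_id`, `gene_id`,
#'   `transcript_id` carried through.
#' @export
score_variants <- function(variants, queries, support,
                           config = scoring_config()) {
  v <- variants[!variants$synonymous, , drop = FALSE]
  sets <- list()
  rows <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    pid <- v$protein_id[i]
    if (is.null(sets[[pid]])) {
      sup <- support[[pid]]
      sets[[pid]] <- if (is.null(sup) || length(sup) == 0L) NA else
        supporting_set(queries[[pid]], sup, config)
    }
    row <- if (identical(sets[[pid]], NA))
      score_result_row(pid, v$description[i], NA_real_, config, 0L, 0L)
    else
      delta_score(sets[[pid]], v$mutant_seq[i], config = config,
                  protein_id = pid)
    row$variant <- v$description[i]
    rows[[i]] <- cbind(data.frame(line_id = v$line_id[i],
                                  gene_id = v$gene_id[i],
                                  transcript_id = v$transcript_id[i],
                                  stringsAsFactors = FALSE), row)
  }
  if (!length(rows))
    return(data.frame(line_id = character(), gene_id = character(),
                      transcript_id = character(), protein_id = character(),
                      variant = character(), score = numeric(),
                      classification = character(), n_clusters = integer(),
                      n_supporting = integer(), flags = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Reduce alternative-transcript scores to one gene-level score
#'
#' When alternative transcripts of a gene are scored separately, the
#' gene is assigned the minimum score over its scored transcript
#' variants, and the classification is recomputed from that score. If
#' every transcript is unscored the gene-level result is unscored.
#'
#' @param transcript_results Data frame of score rows for one gene and
#'   one line.
#' @param config A [scoring_config()] (for the threshold).
#' @return A one-row data frame.
#' @export
gene_level_score <- function(transcript_results, config = scoring_config()) {
  stopifnot(nrow(transcript_results) >= 1L)
  scored <- transcript_results[!is.na(transcript_results$score), , drop = FALSE]
  if (nrow(scored) == 0L) return(transcript_results[1L, , drop = FALSE])
  best <- scored[which.min(scored$score), , drop = FALSE]
  best$classification <- if (best$score < config$threshold) "deleterious"
                         else "neutral"
  best
}

#' Collapse a score table to one row per line and gene
#'
#' @param results Data frame from [score_variants()].
#' @param config A [scoring_config()].
#' @return Data frame with one gene-level score per (line, gene).
#' @export
reduce_to_genes <- function(results, config = scoring_config()) {
  if (nrow(results) == 0L) return(results)
  parts <- split(results, list(results$line_id, results$gene_id), drop = TRUE)
  out <- do.call(rbind, lapply(parts, gene_level_score, config = config))
  rownames(out) <- NULL
  out
}

#' Summarize scored variants by mutation type
#'
#' Tabulates scored results into the five mutation categories
#' (single amino-acid substitution, duplication, deletion, insertion,
#' complex) with counts and score extrema. Complex covers proteins
#' where more than one kind of change occurred (deletion-insertions).
#'
#' @param results Data frame with `variant` and `score` columns.
#' @return Data frame with columns `type`, `n`, `max_score`,
#'   `min_score`.
#' @export
summarize_by_variant_type <- function(results) {
  scored <- results[!is.na(results$score), , drop = FALSE]
  type <- variant_type(scored$variant)
  levels <- c("single aa substitution", "duplication", "deletion",
              "insertion", "complex")
  out <- do.call(rbind, lapply(levels, function(tp) {
    s <- scored$score[!is.na(type) & type == tp]
    data.frame(type = tp, n = length(s),
               max_score = if (length(s)) max(s) else NA_real_,
               min_score = if (length(s)) min(s) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out[out$n > 0L, , drop = FALSE]
}

#' Cluster and supporting-sequence QC report
#'
#' Reports, over unique proteins, how many were scored from fewer than
#' 30 clusters and fewer than 50 supporting sequences, with the
#' corresponding percentages (rounded to whole percent, as usually
#' reported).
#'
#' @param results Score table with `protein_id`, `n_clusters`,
#'   `n_supporting`.
#' @return List with counts, denominators, and percentages.
#' @export
cluster_support_report <- function(results) {
  per_protein <- results[!duplicated(results$protein_id), , drop = FALSE]
  n <- nrow(per_protein)
  few_cl <- sum(per_protein$n_clusters < 30L)
  few_sup <- sum(per_protein$n_supporting < 50L)
  list(n_proteins = n,
       n_few_clusters = few_cl,
       n_few_support = few_sup,
       pct_few_clusters = round(100 * few_cl / n),
       pct_few_support = round(100 * few_sup / n))
}
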