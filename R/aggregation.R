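#' Per-line summary statistics
#'
#' Collapses one MA line's gene-level scores into the summary counts
#' used as fitness predictors:
#' \describe{
#'   \item{psi_tot}{number of scored mutant proteins}
#'   \item{psi_del}{number with score strictly below the threshold}
#'   \item{psi_abs}{number with |score| strictly above |threshold|}
#'   \item{psi_non_del}{`psi_tot - psi_del`}
#'   \item{sigma_tot}{`log(1 - sum of scores)`, `NA` with the
#'     `sigma_undefined` flag when the sum of scores reaches 1}
#' }
#' plus the same counts restricted to an essential-gene list and the
#' tally of unscored proteins, which are excluded from every statistic.
#'
#' @param results Gene-level score rows for one line (see
#'   [reduce_to_genes()]).
#' @param essential_genes Character vector of essential gene ids, or
#'   `NULL` to skip the essential-subset columns.
#' @param threshold Deleterious cutoff (default -2.5).
#' @param relative_genome_size Optional per-line covariate (default 1).
#' @param ancestor_id Carried into the row when supplied.
#' @return One-row data frame of class `line_summary`.
#' @export
summarize_line <- function(results, essential_genes = NULL, threshold = -2.5,
                           relative_genome_size = 1,
                           ancestor_id = NA_character_) {
  line_ids <- unique(results$line_id)
  if (length(line_ids) > 1L)
    stop("summarize_line received rows from several lines: ",
         paste(line_ids, collapse = ", "))
  line_id <- if (length(line_ids)) line_ids else NA_character_
  scored <- results[!is.na(results$score), , drop = FALSE]
  counts <- function(df) {
    c(tot = nrow(df),
      del = sum(df$score < threshold),
      abs = sum(abs(df$score) > abs(threshold)))
  }
  tot <- counts(scored)
  ess <- if (!is.null(essential_genes))
    counts(scored[scored$gene_id %in% essential_genes, , drop = FALSE])
  else c(tot = NA_integer_, del = NA_integer_, abs = NA_integer_)
  ssum <- sum(scored$score)
  sigma_ok <- nrow(scored) == 0L || ssum < 1
  sigma_tot <- if (sigma_ok) log(1 - ifelse(nrow(scored) == 0L, 0, ssum))
               else NA_real_
  ess_scored <- if (!is.null(essential_genes))
    scored[scored$gene_id %in% essential_genes, , drop = FALSE] else NULL
  sigma_tot_ess <- if (is.null(ess_scored)) NA_real_
    else if (nrow(ess_scored) == 0L) 0
    else if (sum(ess_scored$score) < 1) log(1 - sum(ess_scored$score))
    else NA_real_
  out <- data.frame(
    line_id = line_id, ancestor_id = ancestor_id,
    psi_tot = unname(tot["tot"]), psi_del = unname(tot["del"]),
    psi_abs = unname(tot["abs"]),
    psi_non_del = unname(tot["tot"] - tot["del"]),
    psi_tot_ess = unname(ess["tot"]), psi_del_ess = unname(ess["del"]),
    psi_abs_ess = unname(ess["abs"]),
    sigma_tot = sigma_tot, sigma_tot_ess = sigma_tot_ess,
    sigma_undefined = !sigma_ok,
    n_unscored = sum(is.na(results$score)),
    relative_genome_size = relative_genome_size,
    stringsAsFactors = FALSE)
  class(out) <- c("line_summary", class(out))
  out
}

#' Summarize every line of a study
#'
#' @param results Gene-level score table for all lines.
#' @param line_ids Lines to summarize; defaults to those present in
#'   `results`. Lines without rows get all-zero counts (a line with no
#'   nonsynonymous mutations still has a summary).
#' @param ancestors Optional named vector mapping line_id to
#'   ancestor_id.
#' @param genome_sizes Optional named vector of relative genome sizes.
#' @inheritParams summarize_line
#' @return Data frame with one row per line.
#' @export
summarize_lines <- function(results, essential_genes = NULL, threshold = -2.5,
                            line_ids = NULL, ancestors = NULL,
                            genome_sizes = NULL) {
  if (is.null(line_ids)) line_ids <- unique(results$line_id)
  rows <- lapply(line_ids, function(l) {
    r <- results[results$line_id == l, , drop = FALSE]
    r$line_id <- rep(l, nrow(r))
    summarize_line(
      r, essential_genes = essential_genes, threshold = threshold,
      relative_genome_size =
        if (!is.null(genome_sizes) && l %in% names(genome_sizes))
          unname(genome_sizes[[l]]) else 1,
      ancestor_id = if (!is.null(ancestors) && l %in% names(ancestors))
        unname(ancestors[[l]]) else NA_character_)
  })
  out <- do.call(rbind, rows)
  out$line_id <- line_ids
  rownames(out) <- NULL
  out
}

#' Per-ancestor study bookkeeping table
#'
#' Tabulates, for each ancestral background: the number of unique
#' mutated proteins across its MA lines (each protein counted once per
#' ancestor, however many lines carry variants in it), how many of
#' those proteins already carried ancestral variants relative to the
#' reference, the number of MA lines, and the number of protein
#' variants submitted for scoring (every change to a protein in any
#' line counted). A `Total` row holds the column sums.
#'
#' @param variant_records Data frame with one row per submitted protein
#'   variant: columns `line_id`, `protein_id`, and logical
#'   `ancestral_divergent`.
#' @param line_ancestors Named character vector mapping every line_id
#'   to its ancestor_id; an unmapped line is an error.
#' @return Data frame with columns `ancestor_id`, `n_mutated_proteins`,
#'   `n_prior_variant_proteins`, `n_lines`, `n_protein_variants`.
#' @export
summarize_study <- function(variant_records, line_ancestors) {
  unknown <- setdiff(unique(variant_records$line_id), names(line_ancestors))
  if (length(unknown))
    stop("line(s) with no ancestor mapping: ", paste(unknown, collapse = ", "))
  anc <- unname(line_ancestors[variant_records$line_id])
  rows <- lapply(unique(unname(line_ancestors)), function(a) {
    rec <- variant_records[anc == a, , drop = FALSE]
    prot <- rec[!duplicated(rec$protein_id), , drop = FALSE]
    data.frame(ancestor_id = a,
               n_mutated_proteins = nrow(prot),
               n_prior_variant_proteins = sum(prot$ancestral_divergent),
               n_lines = length(unique(names(line_ancestors)[
                 unname(line_ancestors) == a])),
               n_protein_variants = nrow(rec),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(ancestor_id = "Total",
                      n_mutated_proteins = sum(out$n_mutated_proteins),
                      n_prior_variant_proteins = sum(out$n_prior_variant_proteins),
                      n_lines = sum(out$n_lines),
                      n_protein_variants = sum(out$n_protein_variants),
                      stringsAsFactors = FALSE)
  rbind(out, total)
}

#' Remove excluded lines
#'
#' Drops listed lines from a per-line table, logging each exclusion
#' with its reason. Ids not present in the table produce a warning and
#' are otherwise ignored.
#'
#' @param lines Data frame with a `line_id` column.
#' @param exclusions Data frame with `line_id` and `reason`, or `NULL`.
#' @return The filtered data frame.
#' @export
apply_exclusions <- function(lines, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0L) return(lines)
  unknown <- setdiff(exclusions$line_id, lines$line_id)
  if (length(unknown))
    warning("exclusion list names unknown line(s): ",
            paste(unknown, collapse = ", "))
  hit <- exclusions[exclusions$line_id %in% lines$line_id, , drop = FALSE]
  for (i in seq_len(nrow(hit)))
    message("excluding line ", hit$line_id[i], ": ", hit$reason[i])
  lines[!lines$line_id %in% exclusions$line_id, , drop = FALSE]
}
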