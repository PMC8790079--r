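#' Splice the coding sequence from a gene model
#'
#' Concatenates the exon intervals of a gene model in genomic order and
#' reverse-complements the result for minus-strand transcripts, yielding
#' the coding sequence in transcript orientation.
#'
#' @param model A [gene_model()].
#' @param genomic_seq Optional replacement genomic sequence (same span as
#'   the model's); used internally after in-silico mutagenesis.
#' @return Coding sequence as an upper-case character string.
#' @export
splice_cds <- function(model, genomic_seq = NULL) {
  seq <- if (is.null(genomic_seq)) model$genomic_seq else toupper(genomic_seq)
  rel_start <- model$exon_starts - model$seq_offset + 1L
  rel_end <- model$exon_ends - model$seq_offset + 1L
  if (any(rel_start < 1L) || any(rel_end > nchar(seq)))
    stop("exon outside the genomic sequence for transcript ",
         model$transcript_id)
  cds <- paste(substring(seq, rel_start, rel_end), collapse = "")
  if (model$strand == "-")
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  cds
}

#' Apply genomic variants to a sequence
#'
#' Applies a set of anchored VCF-style variants (1-based coordinates,
#' first reference base shared for indels) to a nucleotide sequence.
#' Edits are applied from the highest genomic position to the lowest so
#' that earlier coordinates remain valid. All variants are applied
#' jointly; overlapping variants or a reference-allele mismatch are
#' errors.
#'
#' @param genomic_seq Nucleotide string.
#' @param variants Data frame with columns `position`, `ref`, `alt`.
#' @param seq_offset Genomic coordinate of the first base of
#'   `genomic_seq` (default 1).
#' @return The mutated sequence.
#' @export
apply_genomic_variants <- function(genomic_seq, variants, seq_offset = 1L) {
  genomic_seq <- toupper(genomic_seq)
  if (is.null(variants) || nrow(variants) == 0L) return(genomic_seq)
  v <- variants[order(variants$position, decreasing = TRUE), , drop = FALSE]
  span_start <- v$position
  span_end <- v$position + nchar(v$ref) - 1L
  if (nrow(v) > 1L) {
    ## sorted descending: variant i must start after variant i+1 ends
    if (any(span_start[-nrow(v)] <= span_end[-1L]))
      stop("overlapping variants (positions ",
           paste(v$position[c(span_start[-nrow(v)] <= span_end[-1L], FALSE) |
                            c(FALSE, span_start[-nrow(v)] <= span_end[-1L])],
                 collapse = ", "), ")")
  }
  for (i in seq_len(nrow(v))) {
    rel <- v$position[i] - seq_offset + 1L
    if (rel < 1L || rel + nchar(v$ref[i]) - 1L > nchar(genomic_seq))
      stop("variant at position ", v$position[i],
           " outside the genomic sequence")
    have <- substr(genomic_seq, rel, rel + nchar(v$ref[i]) - 1L)
    if (have != v$ref[i])
      stop("reference allele mismatch at position ", v$position[i],
           ": sequence has '", have, "', table says '", v$ref[i], "'")
    genomic_seq <- paste0(substr(genomic_seq, 1L, rel - 1L), v$alt[i],
                          substring(genomic_seq, rel + nchar(v$ref[i])))
  }
  genomic_seq
}

#' Translate a coding sequence
#'
#' Standard genetic code. Translation stops at the first stop codon, so
#' premature stops truncate the protein; a trailing partial codon is
#' dropped with a warning. Ambiguous (non-ACGT) nucleotides are an
#' error.
#'
#' @param cds Coding sequence (length at least 3).
#' @return Protein string (no stop character).
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) < 3L) stop("coding sequence shorter than one codon")
  if (grepl("[^ACGT]", cds))
    stop("ambiguous nucleotide in coding sequence: ",
         gsub("[ACGT]", "", cds))
  extra <- nchar(cds) %% 3L
  if (extra) {
    warning("dropping trailing partial codon (", extra, " nt)")
    cds <- substr(cds, 1L, nchar(cds) - extra)
  }
  ## plain codon-table translation: the first codon is not treated as
  ## an initiator (CTG/TTG stay L, not M)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) aa <- substr(aa, 1L, stop_at - 1L)
  aa
}

longest_common_prefix <- function(a, b) {
  k <- min(length(a), length(b))
  if (k == 0L) return(0L)
  neq <- which(a[seq_len(k)] != b[seq_len(k)])
  if (length(neq)) neq[1L] - 1L else k
}

#' Describe the difference between a query and a mutant protein
#'
#' Trims the longest common prefix (then the longest common suffix of
#' the remainder, which places ambiguous indels at their 3'-most
#' equivalent position) and classifies the remaining edit as a
#' substitution, deletion, insertion, duplication, or
#' deletion-insertion. Truncations come out as deletions running to the
#' query's last residue. Equal sequences yield a synonymous sentinel
#' (`description` is `NA`, `synonymous` is `TRUE`): only nonsynonymous
#' changes are scored downstream.
#'
#' Insertions at the very first or last position of the query have no
#' flanking residue pair and are encoded as a single-residue
#' deletion-insertion so that every description round-trips through
#' [parse_variant()].
#'
#' @param query,mutant Protein sequences.
#' @param protein_id Optional identifier carried into the record.
#' @return A `protein_variant` list (see [parse_variant()]) with an
#'   extra logical element `synonymous`.
#' @export
diff_proteins <- function(query, mutant, protein_id = NA_character_) {
  query <- toupper(query); mutant <- toupper(mutant)
  out <- function(description, synonymous = FALSE) {
    structure(list(protein_id = protein_id, description = description,
                   query_len = nchar(query), mutant_seq = mutant,
                   synonymous = synonymous),
              class = "protein_variant")
  }
  if (query == mutant) return(out(NA_character_, synonymous = TRUE))

  qa <- strsplit(query, "")[[1]]
  ma <- strsplit(mutant, "")[[1]]
  n <- length(qa); m <- length(ma)
  p <- longest_common_prefix(qa, ma)
  s <- longest_common_prefix(rev(qa[seq_len(n - p) + p]),
                             rev(ma[seq_len(m - p) + p]))
  qseg <- if (p + 1L <= n - s) paste(qa[(p + 1L):(n - s)], collapse = "") else ""
  mseg <- if (p + 1L <= m - s) paste(ma[(p + 1L):(m - s)], collapse = "") else ""
  qlen <- nchar(qseg); mlen <- nchar(mseg)
  at <- function(i) qa[i]

  if (qlen == 1L && mlen == 1L)
    return(out(paste0(qseg, p + 1L, mseg)))
  if (mlen == 0L) {
    if (qlen == 1L) return(out(paste0(qseg, p + 1L, "del")))
    return(out(paste0(at(p + 1L), p + 1L, "_", at(n - s), n - s, "del")))
  }
  if (qlen == 0L) {
    ## pure insertion after position p
    if (p >= mlen &&
        paste(qa[(p - mlen + 1L):p], collapse = "") == mseg) {
      if (mlen == 1L) return(out(paste0(at(p), p, "dup")))
      return(out(paste0(at(p - mlen + 1L), p - mlen + 1L, "_", at(p), p, "dup")))
    }
    if (p == 0L)
      return(out(paste0(at(1L), 1L, "delins", mseg, at(1L))))
    if (p == n)
      return(out(paste0(at(n), n, "delins", at(n), mseg)))
    return(out(paste0(at(p), p, "_", at(p + 1L), p + 1L, "ins", mseg)))
  }
  if (qlen == 1L)
    return(out(paste0(qseg, p + 1L, "delins", mseg)))
  out(paste0(at(p + 1L), p + 1L, "_", at(n - s), n - s, "delins", mseg))
}

#' Build the ancestor query protein from the reference protein
#'
#' Applies protein-level ancestral variant descriptions to the
#' reference protein, producing the MA ancestor's sequence. Downstream
#' variant descriptions are then taken against this query, never
#' against the reference, which removes reference bias from the scores.
#' Descriptions use reference coordinates and are applied from the
#' highest position downward.
#'
#' @param reference_protein Reference protein sequence.
#' @param ancestral_variants Character vector of variant descriptions
#'   (may be empty).
#' @return The ancestor query protein sequence.
#' @export
build_ancestor_query <- function(reference_protein, ancestral_variants) {
  if (length(ancestral_variants) == 0L) return(toupper(reference_protein))
  pos <- as.integer(sub("^[A-Z]([0-9]+).*$", "\\1", ancestral_variants))
  seq <- toupper(reference_protein)
  for (d in ancestral_variants[order(pos, decreasing = TRUE)])
    seq <- parse_variant(d, seq)$mutant_seq
  seq
}

## Locate the exon (index) containing a variant's full reference span,
## NA when the span lies entirely outside all exons; error when it
## straddles an exon boundary.
exon_of_variant <- function(model, position, ref) {
  span_end <- position + nchar(ref) - 1L
  inside <- which(model$exon_starts <= position & model$exon_ends >= span_end)
  if (length(inside)) return(inside[1L])
  touches <- any(model$exon_starts <= span_end & model$exon_ends >= position)
  if (touches)
    stop("variant at position ", position,
         " straddles an exon boundary of transcript ", model$transcript_id)
  NA_integer_
}

#' Mutate one transcript in silico
#'
#' Applies a line's genomic variants to a transcript's genomic
#' sequence, shifts exon boundaries downstream of indels, splices, and
#' translates. Variants falling entirely outside exons do not affect
#' the protein and are skipped with a message.
#'
#' @param model A [gene_model()].
#' @param variants Data frame with `position`, `ref`, `alt` (genomic
#'   coordinates on the reference).
#' @return List with `cds`, `protein`, and `skipped` (row indices of
#'   non-exonic variants).
#' @export
mutate_transcript <- function(model, variants) {
  if (is.null(variants) || nrow(variants) == 0L) {
    cds <- splice_cds(model)
    return(list(cds = cds, protein = translate_cds(cds), skipped = integer()))
  }
  exon_idx <- vapply(seq_len(nrow(variants)), function(i)
    exon_of_variant(model, variants$position[i], variants$ref[i]), integer(1))
  skipped <- which(is.na(exon_idx))
  if (length(skipped))
    message("transcript ", model$transcript_id, ": skipping ",
            length(skipped), " non-exonic variant(s)")
  v <- variants[!is.na(exon_idx), , drop = FALSE]
  mut_seq <- apply_genomic_variants(model$genomic_seq, v, model$seq_offset)
  delta <- if (nrow(v)) nchar(v$alt) - nchar(v$ref) else integer()
  shift_of <- function(b)
    sum(delta[v$position + nchar(v$ref) - 1L <= b])
  new_model <- model
  new_model$exon_starts <- vapply(model$exon_starts,
                                  function(b) b + shift_of(b - 1L), numeric(1))
  new_model$exon_ends <- vapply(model$exon_ends, shift_of, numeric(1)) +
    model$exon_ends
  new_model$exon_starts <- as.integer(new_model$exon_starts)
  new_model$exon_ends <- as.integer(new_model$exon_ends)
  cds <- splice_cds(new_model, mut_seq)
  list(cds = cds, protein = translate_cds(cds), skipped = skipped)
}

## Compose a line's variants with the ancestral variants of the same
## gene. A line variant whose anchored position collides with an
## ancestral variant is interpreted as called on the ancestral
## background: the composed edit carries the ancestral ref and the line
## alt, and drops out entirely when they agree (a true reversion).
compose_variants <- function(ancestral, line) {
  if (is.null(ancestral) || nrow(ancestral) == 0L) return(line)
  if (is.null(line) || nrow(line) == 0L) return(ancestral)
  keep_anc <- rep(TRUE, nrow(ancestral))
  out <- line
  for (i in seq_len(nrow(line))) {
    j <- which(ancestral$position == line$position[i])
    if (length(j) == 1L) {
      if (line$ref[i] != ancestral$alt[j])
        stop("variant at position ", line$position[i],
             " collides with an ancestral variant but its ref allele ",
             "matches neither the reference nor the ancestral allele")
      keep_anc[j] <- FALSE
      out$ref[i] <- ancestral$ref[j]
    }
  }
  out <- out[out$ref != out$alt, , drop = FALSE]
  rbind(ancestral[keep_anc, c("position", "ref", "alt"), drop = FALSE],
        out[, c("position", "ref", "alt"), drop = FALSE])
}

#' Run the mutagenesis stage over a study
#'
#' For every transcript of every mutated gene, builds the ancestor
#' query protein (reference plus any ancestral variants), applies each
#' line's variants jointly on top of the ancestral background, and
#' describes the resulting protein change against the ancestor query.
#' Alternative transcripts of one gene are processed independently;
#' gene-level reduction happens in scoring.
#'
#' @param gene_models Named list of [gene_model()] objects.
#' @param mutations Data frame of per-line genomic variants (columns
#'   `line_id`, `gene_id`, `position`, `ref`, `alt`).
#' @param ancestral_variants Optional data frame of ancestor-vs-reference
#'   variants (columns `gene_id`, `position`, `ref`, `alt`).
#' @return List with `variants` (one row per line x transcript:
#'   `line_id`, `gene_id`, `transcript_id`, `protein_id`, `description`,
#'   `mutant_seq`, `synonymous`, `ancestral_divergent`), `queries`
#'   (named character vector of ancestor query proteins, one per
#'   transcript), and `references` (reference proteins).
#' @export
mutate_study <- function(gene_models, mutations, ancestral_variants = NULL) {
  stopifnot(is.list(gene_models))
  rows <- list()
  queries <- character()
  references <- character()
  for (model in gene_models) {
    anc <- NULL
    if (!is.null(ancestral_variants))
      anc <- ancestral_variants[ancestral_variants$gene_id == model$gene_id, ,
                                drop = FALSE]
    ref_protein <- translate_cds(splice_cds(model))
    anc_res <- mutate_transcript(model, anc)
    query <- anc_res$protein
    pid <- model$transcript_id
    queries[[pid]] <- query
    references[[pid]] <- ref_protein
    divergent <- !identical(query, ref_protein)

    gene_mut <- mutations[mutations$gene_id == model$gene_id, , drop = FALSE]
    for (line in unique(gene_mut$line_id)) {
      lv <- gene_mut[gene_mut$line_id == line, , drop = FALSE]
      combined <- compose_variants(
        if (is.null(anc)) NULL else anc[, c("position", "ref", "alt"), drop = FALSE],
        lv[, c("position", "ref", "alt"), drop = FALSE])
      res <- mutate_transcript(model, combined)
      d <- diff_proteins(query, res$protein, protein_id = pid)
      rows[[length(rows) + 1L]] <- data.frame(
        line_id = line, gene_id = model$gene_id, transcript_id = pid,
        protein_id = pid, description = d$description,
        mutant_seq = d$mutant_seq, synonymous = d$synonymous,
        ancestral_divergent = divergent, stringsAsFactors = FALSE)
    }
  }
  variants <- if (length(rows)) do.call(rbind, rows) else
    data.frame(line_id = character(), gene_id = character(),
               transcript_id = character(), protein_id = character(),
               description = character(), mutant_seq = character(),
               synonymous = logical(), ancestral_divergent = logical(),
               stringsAsFactors = FALSE)
  list(variants = variants, queries = queries, references = references)
}
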