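#' Read a protein FASTA file
#'
#' Reads a FASTA file into a named character vector. Sequences are
#' upper-cased and alignment gap characters (`-`, `.`) are stripped, so
#' files exported from multiple sequence alignments can be used directly
#' as supporting sequence sets.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(gsub("[-.]", "", as.character(set)))
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

## Shared TSV reader: tab-separated, UTF-8, '#' comment lines ignored.
## CRLF line endings are handled transparently by read.delim.
read_tsv_checked <- function(path, required, label) {
  if (!file.exists(path)) stop(label, " file not found: ", path)
  ## read everything as character: nucleotide alleles like "T" must not
  ## be type-converted (to logical); typed columns are converted after
  ## validation
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(label, " table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genomic mutation table
#'
#' Expects a tab-separated table with mandatory columns `line_id`,
#' `gene_id`, `position`, `ref`, `alt`. Coordinates are 1-based and
#' indels use the anchored VCF-style representation (first reference
#' base shared between `ref` and `alt`). Unknown columns are preserved.
#'
#' @param path Path to a TSV file (`#` lines are comments).
#' @return A data frame of genomic variant records.
#' @export
read_mutation_table <- function(path) {
  df <- read_tsv_checked(path, c("line_id", "gene_id", "position", "ref", "alt"),
                         "mutation")
  df$position <- validate_coordinate(df$position, "position")
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  bad <- !grepl("^[ACGT]+$", df$ref) | !grepl("^[ACGT]+$", df$alt)
  if (any(bad))
    stop("malformed ref/alt allele(s) at row(s): ",
         paste(which(bad), collapse = ", "),
         " (empty or non-ACGT; use anchored VCF-style alleles)")
  same <- df$ref == df$alt
  if (any(same))
    stop("ref equals alt at row(s): ", paste(which(same), collapse = ", "))
  df
}

validate_coordinate <- function(x, what) {
  xi <- suppressWarnings(as.integer(x))
  bad <- is.na(xi) | xi < 1L | (as.numeric(x) != xi)
  if (any(bad))
    stop("malformed ", what, " at row(s): ", paste(which(bad), collapse = ", "),
         " (must be a positive 1-based integer)")
  xi
}

#' Read a replicated growth-rate table
#'
#' Mandatory columns: `line_id`, `role` (`ma` or `control`),
#' `ancestor_id`, `block`, `replicate`, `growth_rate`. An `environment`
#' column is optional and used as a matching factor when present.
#'
#' @param path Path to a TSV file.
#' @return Data frame of growth measurements.
#' @export
read_growth_table <- function(path) {
  df <- read_tsv_checked(path, c("line_id", "role", "ancestor_id", "block",
                                 "replicate", "growth_rate"), "growth")
  df$role <- tolower(as.character(df$role))
  if (!all(df$role %in% c("ma", "control")))
    stop("growth table role column must be 'ma' or 'control'")
  df$growth_rate <- as.numeric(df$growth_rate)
  if (any(!is.finite(df$growth_rate)))
    stop("non-finite growth_rate at row(s): ",
         paste(which(!is.finite(df$growth_rate)), collapse = ", "))
  if (any(df$role == "control")) {
    anc_ma <- unique(df$ancestor_id[df$role == "ma"])
    anc_ctl <- unique(df$ancestor_id[df$role == "control"])
    orphan <- setdiff(anc_ma, anc_ctl)
    if (length(orphan))
      stop("MA ancestor(s) without control rows: ",
           paste(orphan, collapse = ", "))
  }
  df
}

#' Read a per-variant score table
#'
#' Mandatory columns: `protein_id`, `variant`, `score`. The columns
#' written by [score_variants()] (`line_id`, `gene_id`,
#' `classification`, `n_clusters`, `n_supporting`, `flags`) and any
#' others are carried through untouched.
#'
#' @param path Path to a TSV file.
#' @return Data frame of score results; `score` is numeric with `NA`
#'   for unscored variants.
#' @export
read_score_table <- function(path) {
  df <- read_tsv_checked(path, c("protein_id", "variant", "score"), "score")
  df$score <- suppressWarnings(as.numeric(df$score))
  df
}

#' Read a plain-text essential-gene list
#'
#' One gene id per line; `#` lines and blank lines are ignored.
#'
#' @param path Path to the list.
#' @return Character vector of unique gene ids.
#' @export
read_essential_genes <- function(path) {
  if (!file.exists(path)) stop("essential-gene file not found: ", path)
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  unique(x[nzchar(x)])
}

#' Read a line-exclusion table
#'
#' @param path TSV with columns `line_id` and `reason`.
#' @return Data frame of exclusions.
#' @export
read_exclusion_table <- function(path) {
  read_tsv_checked(path, c("line_id", "reason"), "exclusion")
}

#' Construct a gene model
#'
#' A gene model holds the exon structure and genomic sequence of one
#' transcript. Coordinates are 1-based inclusive genomic positions;
#' `seq_offset` is the genomic coordinate of the first base of
#' `genomic_seq` (so a sequence excised around the locus can be used).
#'
#' @param gene_id,transcript_id Identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of equal length; exons
#'   must be sorted by genomic start and non-overlapping.
#' @param genomic_seq Nucleotide string covering the model's span.
#' @param seq_offset Genomic coordinate of `genomic_seq`'s first base.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id, strand, exon_starts, exon_ends,
                       genomic_seq, seq_offset = 1L) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  if (length(exon_starts) != length(exon_ends) || length(exon_starts) == 0L)
    stop("exon_starts and exon_ends must be non-empty and of equal length")
  if (any(exon_ends < exon_starts)) stop("exon end before exon start")
  if (is.unsorted(exon_starts, strictly = TRUE))
    stop("exons must be sorted by genomic start")
  if (length(exon_starts) > 1L &&
      any(exon_starts[-1L] <= exon_ends[-length(exon_ends)]))
    stop("exons overlap")
  genomic_seq <- toupper(genomic_seq)
  seq_offset <- as.integer(seq_offset)
  span_end <- seq_offset + nchar(genomic_seq) - 1L
  if (exon_starts[1L] < seq_offset || exon_ends[length(exon_ends)] > span_end)
    stop("exon interval outside the supplied genomic sequence span")
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 strand = strand, exon_starts = exon_starts,
                 exon_ends = exon_ends, genomic_seq = genomic_seq,
                 seq_offset = seq_offset),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, "/", x$transcript_id, " (", x$strand,
      ") ", length(x$exon_starts), " exon(s), span ",
      x$seq_offset, "-", x$seq_offset + nchar(x$genomic_seq) - 1L, "\n",
      sep = "")
  invisible(x)
}

#' Read gene models from a TSV file
#'
#' One row per transcript with columns `gene_id`, `transcript_id`,
#' `strand`, `exon_starts`, `exon_ends` (comma-separated coordinate
#' lists), `genomic_seq`, and optional `seq_offset` (default 1).
#'
#' @param path Path to a TSV file.
#' @return Named list of [gene_model()] objects keyed by transcript id.
#' @export
read_gene_models <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "transcript_id", "strand",
                                 "exon_starts", "exon_ends", "genomic_seq"),
                         "gene model")
  if (is.null(df$seq_offset)) df$seq_offset <- 1L
  models <- lapply(seq_len(nrow(df)), function(i) {
    gene_model(df$gene_id[i], df$transcript_id[i], df$strand[i],
               as.integer(strsplit(as.character(df$exon_starts[i]), ",")[[1]]),
               as.integer(strsplit(as.character(df$exon_ends[i]), ",")[[1]]),
               df$genomic_seq[i], df$seq_offset[i])
  })
  names(models) <- df$transcript_id
  models
}

#' Write gene models to a TSV file
#'
#' @param models List of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  df <- do.call(rbind, lapply(models, function(m) {
    data.frame(gene_id = m$gene_id, transcript_id = m$transcript_id,
               strand = m$strand,
               exon_starts = paste(m$exon_starts, collapse = ","),
               exon_ends = paste(m$exon_ends, collapse = ","),
               genomic_seq = m$genomic_seq, seq_offset = m$seq_offset,
               stringsAsFactors = FALSE)
  }))
  write_tsv(df, path)
}
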