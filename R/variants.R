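## Protein variant notation: the HGVS protein subset used by PROVEAN-style
## input files, without the "p." prefix. Supported forms:
##   A123T                 substitution
##   K45del, K45_L47del    deletion (single residue / range)
##   K45_L46insQRS         insertion between two adjacent residues
##   K45dup, K43_K45dup    duplication of the immediately preceding run
##   A12delinsGG, A12_Y20delinsGG
##                         deletion-insertion
## Positions are 1-based on the query protein; the reference residues named
## in the description are verified against the query before application.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_residue <- function(query, pos, aa, description) {
  n <- nchar(query)
  if (pos < 1L || pos > n)
    stop("variant '", description, "': position ", pos,
         " outside query of length ", n)
  have <- substr(query, pos, pos)
  if (have != aa)
    stop("variant '", description, "': query has '", have, "' at position ",
         pos, ", description says '", aa, "'")
  invisible(TRUE)
}

#' Parse a protein variant description and apply it to a query
#'
#' Parses one description from the HGVS protein subset (substitution,
#' `del`, `ins`, `dup`, `delins`; no `p.` prefix) and computes the
#' mutant sequence by applying the edit to `query_seq`. Reference
#' residues named in the description are verified against the query;
#' a mismatch or out-of-range position is an error.
#'
#' @param description Variant description, e.g. `"A123T"`, `"K45del"`,
#'   `"K45_L46insQ"`, `"A12_Y20delinsGG"`, `"K45dup"`.
#' @param query_seq Query (wild-type) protein sequence.
#' @param protein_id Optional identifier carried through to the result.
#' @return A list of class `protein_variant` with elements `protein_id`,
#'   `description`, `query_len`, and `mutant_seq`.
#' @export
parse_variant <- function(description, query_seq, protein_id = NA_character_) {
  description <- trimws(description)
  query_seq <- toupper(query_seq)
  n <- nchar(query_seq)
  res <- function(mutant) {
    structure(list(protein_id = protein_id, description = description,
                   query_len = n, mutant_seq = mutant),
              class = "protein_variant")
  }

  m <- regmatches(description,
                  regexec("^([A-Z])([0-9]+)_([A-Z])([0-9]+)(del|dup)$", description))[[1]]
  if (length(m)) {
    s <- as.integer(m[3]); e <- as.integer(m[5])
    if (e < s) stop("variant '", description, "': range end before start")
    check_residue(query_seq, s, m[2], description)
    check_residue(query_seq, e, m[4], description)
    seg <- substr(query_seq, s, e)
    if (m[6] == "del")
      return(res(paste0(substr(query_seq, 1L, s - 1L),
                        substring(query_seq, e + 1L))))
    return(res(paste0(substr(query_seq, 1L, e), seg,
                      substring(query_seq, e + 1L))))
  }

  m <- regmatches(description,
                  regexec("^([A-Z])([0-9]+)(del|dup)$", description))[[1]]
  if (length(m)) {
    p <- as.integer(m[3])
    check_residue(query_seq, p, m[2], description)
    if (m[4] == "del")
      return(res(paste0(substr(query_seq, 1L, p - 1L),
                        substring(query_seq, p + 1L))))
    return(res(paste0(substr(query_seq, 1L, p), substr(query_seq, p, p),
                      substring(query_seq, p + 1L))))
  }

  m <- regmatches(description,
                  regexec("^([A-Z])([0-9]+)_([A-Z])([0-9]+)ins([A-Z]+)$", description))[[1]]
  if (length(m)) {
    s <- as.integer(m[3]); e <- as.integer(m[5])
    if (e != s + 1L)
      stop("variant '", description, "': insertion flanks must be adjacent")
    check_residue(query_seq, s, m[2], description)
    check_residue(query_seq, e, m[4], description)
    return(res(paste0(substr(query_seq, 1L, s), m[6],
                      substring(query_seq, s + 1L))))
  }

  m <- regmatches(description,
                  regexec("^([A-Z])([0-9]+)_([A-Z])([0-9]+)delins([A-Z]+)$", description))[[1]]
  if (length(m)) {
    s <- as.integer(m[3]); e <- as.integer(m[5])
    if (e < s) stop("variant '", description, "': range end before start")
    check_residue(query_seq, s, m[2], description)
    check_residue(query_seq, e, m[4], description)
    return(res(paste0(substr(query_seq, 1L, s - 1L), m[6],
                      substring(query_seq, e + 1L))))
  }

  m <- regmatches(description,
                  regexec("^([A-Z])([0-9]+)delins([A-Z]+)$", description))[[1]]
  if (length(m)) {
    p <- as.integer(m[3])
    check_residue(query_seq, p, m[2], description)
    return(res(paste0(substr(query_seq, 1L, p - 1L), m[4],
                      substring(query_seq, p + 1L))))
  }

  m <- regmatches(description,
                  regexec("^([A-Z])([0-9]+)([A-Z])$", description))[[1]]
  if (length(m)) {
    p <- as.integer(m[3])
    check_residue(query_seq, p, m[2], description)
    return(res(paste0(substr(query_seq, 1L, p - 1L), m[4],
                      substring(query_seq, p + 1L))))
  }

  stop("unrecognized variant description: '", description, "'")
}

#' @export
print.protein_variant <- function(x, ...) {
  cat("<protein_variant> ", if (!is.na(x$protein_id)) paste0(x$protein_id, " "),
      x$description, " (query ", x$query_len, " aa -> mutant ",
      nchar(x$mutant_seq), " aa)\n", sep = "")
  invisible(x)
}

#' Classify a variant description by mutation type
#'
#' Maps a description from the supported notation onto the summary
#' categories used for score tables: single amino-acid substitution,
#' duplication, deletion, insertion, or complex (a deletion-insertion,
#' which arises when several kinds of change hit the same protein).
#'
#' @param description Character vector of variant descriptions.
#' @return Character vector of types.
#' @export
variant_type <- function(description) {
  vapply(description, function(d) {
    if (is.na(d)) return(NA_character_)
    if (grepl("delins", d)) "complex"
    else if (grepl("dup$", d)) "duplication"
    else if (grepl("del$", d)) "deletion"
    else if (grepl("ins[A-Z]+$", d)) "insertion"
    else if (grepl("^[A-Z][0-9]+[A-Z]$", d)) "single aa substitution"
    else NA_character_
  }, character(1), USE.NAMES = FALSE)
}
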