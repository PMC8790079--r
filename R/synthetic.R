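#' Simulation configuration for a synthetic MA study
#'
#' Defines the conditions of a generated mutation-accumulation study:
#' a set of proteins with site-specific conservation, homologous
#' supporting sequences derived from each protein, MA lines carrying
#' Poisson numbers of genomic mutations, and replicated growth assays
#' with block structure and matched ancestral controls.
#'
#' True line fitness is additive over mutations (no epistasis,
#' matching the regression models under study) and linked to the
#' realized delta scores according to `effect_model`:
#' \describe{
#'   \item{uniform_per_mutation}{each scored mutant protein shifts
#'     fitness by `effect_size` (default -0.04), regardless of score —
#'     the regime where the plain mutant-protein count is the right
#'     predictor;}
#'   \item{score_linked}{each scored mutant protein contributes
#'     `effect_size * score` (default 0.005 per score unit) — the
#'     regime where the aggregate score carries real information;}
#'   \item{deleterious_linked}{as `score_linked` but only proteins
#'     scoring below `effect_cutoff` (default -2) contribute — the
#'     regime where an interior deleterious threshold is optimal.}
#' }
#'
#' @param seed Integer seed; mandatory, there is no implicit entropy.
#' @param n_ancestors Ancestral backgrounds (default 2).
#' @param n_lines_per_ancestor MA lines per background (default 10).
#' @param n_proteins Proteins in the genome (default 25).
#' @param protein_length_mean Mean protein length in aa (default 60).
#' @param n_supporting_per_protein Homologs per supporting set
#'   (default 8).
#' @param conservation_profile Function of `n` returning per-site
#'   substitution tolerances in \[0, 1\]; the default draws strongly
#'   conserved sites (tolerance 0.02) with probability 0.4 and
#'   tolerant sites (uniform on \[0.2, 0.9\]) otherwise.
#' @param mutation_rate_per_line Poisson mean of genomic mutations per
#'   line (default 2.5).
#' @param effect_model One of `"uniform_per_mutation"`,
#'   `"score_linked"`, `"deleterious_linked"`.
#' @param effect_size Effect scale; `NULL` picks the per-model default
#'   above.
#' @param effect_cutoff Score cutoff for `deleterious_linked`
#'   (default -2).
#' @param indel_prob Probability that a mutation is a short indel
#'   rather than a SNV (default 0.06, split evenly).
#' @param missense_only When `TRUE`, redraw mutations that truncate the
#'   protein (nonsense changes). Used for score-linked regimes, where
#'   effects proportional to the score only make sense for missense
#'   variants: truncation scores are extreme alignment artifacts, not
#'   proportional effect measurements (default `FALSE`).
#' @param replicate_sd Assay noise sd per measurement (default 0.02).
#' @param n_blocks Assay blocks; each line is measured once per block
#'   (default 3).
#' @param block_sd Sd of block effects (default 0.01).
#' @param n_controls_per_ancestor Control (ancestor) lines per
#'   background (default 4).
#' @param ancestral_variant_rate Fraction of proteins carrying
#'   ancestral variants relative to the reference (default 0.15).
#' @param base_growth Mean ancestral growth rate (default 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed, n_ancestors = 2L, n_lines_per_ancestor = 10L,
                       n_proteins = 25L, protein_length_mean = 60,
                       n_supporting_per_protein = 8L,
                       conservation_profile = NULL,
                       mutation_rate_per_line = 2.5,
                       effect_model = c("uniform_per_mutation",
                                        "score_linked",
                                        "deleterious_linked"),
                       effect_size = NULL, effect_cutoff = -2,
                       indel_prob = 0.06, missense_only = FALSE,
                       replicate_sd = 0.02,
                       n_blocks = 3L, block_sd = 0.01,
                       n_controls_per_ancestor = 4L,
                       ancestral_variant_rate = 0.15, base_growth = 1) {
  if (missing(seed)) stop("seed is mandatory")
  effect_model <- match.arg(effect_model)
  if (is.null(effect_size))
    effect_size <- switch(effect_model,
                          uniform_per_mutation = -0.04,
                          score_linked = 0.005,
                          deleterious_linked = 0.005)
  if (is.null(conservation_profile))
    conservation_profile <- function(n)
      ifelse(stats::runif(n) < 0.4, 0.02, stats::runif(n, 0.2, 0.9))
  stopifnot(mutation_rate_per_line >= 0, replicate_sd >= 0, block_sd >= 0,
            ancestral_variant_rate >= 0, indel_prob >= 0, indel_prob < 1)
  structure(as.list(environment()), class = "sim_config")
}

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

#' Simulate a protein family
#'
#' Generates a query protein and a supporting set of homologs derived
#' from it by per-site substitution with probability equal to each
#' site's tolerance, so conserved sites stay invariant across the set
#' and substitutions at them receive more negative delta scores than
#' substitutions at tolerant sites.
#'
#' @param length Protein length.
#' @param n_support Number of supporting sequences.
#' @param tolerance Per-site tolerance vector (recycled); `NULL` draws
#'   from the default profile of [sim_config()].
#' @param query_id Id used to name the output sequences.
#' @return List with `query`, `support` (named character vector), and
#'   `tolerance`.
#' @export
simulate_family <- function(length, n_support, tolerance = NULL,
                            query_id = "q1") {
  if (is.null(tolerance))
    tolerance <- ifelse(stats::runif(length) < 0.4, 0.02,
                        stats::runif(length, 0.2, 0.9))
  tolerance <- rep_len(tolerance, length)
  query <- random_protein(length)
  qa <- strsplit(query, "")[[1]]
  support <- vapply(seq_len(n_support), function(j) {
    flip <- stats::runif(length) < tolerance
    s <- qa
    if (any(flip))
      s[flip] <- vapply(s[flip], function(a)
        sample(setdiff(AA20, a), 1L), character(1))
    paste(s, collapse = "")
  }, character(1))
  names(support) <- paste0(query_id, "_h", seq_len(n_support))
  list(query = query, support = support, tolerance = tolerance)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

codons_for <- function(aa_vec) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  vapply(aa_vec, function(a) sample(by_aa[[a]], 1L), character(1))
}

random_intron <- function() {
  paste0("GT", paste(sample(c("A", "C", "G", "T"), sample(4:8, 1L),
                            replace = TRUE), collapse = ""), "AG")
}

#' Simulate a gene model encoding a given protein
#'
#' Reverse-engineers a coding sequence for the protein (random
#' synonymous codons plus a stop codon), splits it over 1-3 exons with
#' random short introns, and places it on a random strand, such that
#' [splice_cds()] followed by [translate_cds()] reproduces the protein
#' exactly.
#'
#' @param protein Protein sequence to encode.
#' @param gene_id,transcript_id Identifiers.
#' @param n_exons Number of exons (default random in 1-3).
#' @return A [gene_model()].
#' @export
simulate_gene_model <- function(protein, gene_id, transcript_id,
                                n_exons = sample(1:3, 1L)) {
  cds <- paste0(paste(codons_for(strsplit(protein, "")[[1]]), collapse = ""),
                sample(STOP_CODONS, 1L))
  L <- nchar(cds)
  n_exons <- min(n_exons, L - 1L)
  cuts <- if (n_exons > 1L) sort(sample(seq_len(L - 1L), n_exons - 1L)) else integer()
  bounds <- c(0L, cuts, L)
  pieces <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
  introns <- if (n_exons > 1L) vapply(seq_len(n_exons - 1L),
                                      function(i) random_intron(), character(1))
             else character()
  genomic <- pieces[1L]
  exon_starts <- 1L
  exon_ends <- nchar(pieces[1L])
  for (i in seq_along(introns)) {
    genomic <- paste0(genomic, introns[i])
    exon_starts <- c(exon_starts, nchar(genomic) + 1L)
    genomic <- paste0(genomic, pieces[i + 1L])
    exon_ends <- c(exon_ends, nchar(genomic))
  }
  strand <- sample(c("+", "-"), 1L)
  if (strand == "-") {
    Lg <- nchar(genomic)
    genomic <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(genomic)))
    new_starts <- rev(Lg - exon_ends + 1L)
    exon_ends <- rev(Lg - exon_starts + 1L)
    exon_starts <- new_starts
  }
  gene_model(gene_id, transcript_id, strand, exon_starts, exon_ends, genomic)
}

## ascending genomic positions of exonic bases
exonic_positions <- function(model)
  unlist(Map(seq.int, model$exon_starts, model$exon_ends))

base_at <- function(model, pos)
  substr(model$genomic_seq, pos - model$seq_offset + 1L,
         pos - model$seq_offset + 1L)

other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

## draw one random exonic mutation for a model (anchored VCF style)
draw_mutation <- function(model, indel_prob) {
  pos_pool <- exonic_positions(model)
  kind <- if (stats::runif(1) < indel_prob)
    sample(c("del", "ins"), 1L) else "snv"
  if (kind == "snv") {
    p <- sample(pos_pool, 1L)
    ref <- base_at(model, p)
    return(data.frame(position = p, ref = ref, alt = other_base(ref),
                      stringsAsFactors = FALSE))
  }
  k <- sample(1:3, 1L)
  if (kind == "ins") {
    p <- sample(pos_pool, 1L)
    ref <- base_at(model, p)
    ins <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                 collapse = "")
    return(data.frame(position = p, ref = ref, alt = paste0(ref, ins),
                      stringsAsFactors = FALSE))
  }
  ## deletion: anchor plus k deleted bases, all within one exon
  ex <- which(model$exon_ends - model$exon_starts >= k)
  if (!length(ex)) return(draw_mutation(model, 0))   # fall back to a SNV
  e <- if (length(ex) == 1L) ex else sample(ex, 1L)
  pool <- seq.int(model$exon_starts[e], model$exon_ends[e] - k)
  p <- pool[sample.int(length(pool), 1L)]
  ref <- substr(model$genomic_seq, p - model$seq_offset + 1L,
                p - model$seq_offset + 1L + k)
  data.frame(position = p, ref = ref, alt = substr(ref, 1L, 1L),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic MA study
#'
#' Generates protein families, gene models, ancestral variants, per-line
#' genomic mutation tables, and a replicated growth table whose latent
#' line fitness follows the configured effect model; the realized delta
#' scores that define score-linked effects are computed with the
#' package's own scoring pipeline at generation time. Ancestral
#' variants are placed at tolerant sites (codon second positions of
#' high-tolerance residues), emulating standing variation screened by
#' selection.
#'
#' @param config A [sim_config()].
#' @param scoring A [scoring_config()] used to realize scores.
#' @return List of class `ma_study` with elements `config`,
#'   `gene_models`, `families`, `queries` (ancestor query proteins),
#'   `mutations`, `ancestral_variants`, `growth`, `scores` (gene-level
#'   realized score table), and `truth` (latent per-line fitness and
#'   per-line effect decomposition).
#' @export
simulate_ma_study <- function(config, scoring = scoring_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  ## 1. proteins, families, gene models ---------------------------------
  lens <- pmax(30L, stats::rpois(config$n_proteins,
                                 config$protein_length_mean))
  ids <- sprintf("g%03d", seq_len(config$n_proteins))
  families <- list()
  gene_models <- list()
  for (i in seq_len(config$n_proteins)) {
    tol <- config$conservation_profile(lens[i])
    fam <- simulate_family(lens[i], config$n_supporting_per_protein,
                           tolerance = tol, query_id = ids[i])
    families[[ids[i]]] <- fam
    m <- simulate_gene_model(fam$query, gene_id = ids[i],
                             transcript_id = paste0(ids[i], ".t1"))
    gene_models[[m$transcript_id]] <- m
  }

  ## 2. ancestral variants at tolerant sites ----------------------------
  anc_rows <- list()
  for (i in seq_len(config$n_proteins)) {
    if (stats::runif(1) >= config$ancestral_variant_rate) next
    fam <- families[[ids[i]]]
    m <- gene_models[[paste0(ids[i], ".t1")]]
    tolerant <- which(fam$tolerance >= stats::median(fam$tolerance))
    site <- if (length(tolerant) == 1L) tolerant else sample(tolerant, 1L)
    cds_pos <- 3L * (site - 1L) + 2L          # codon second position
    gpos <- exonic_positions(m)
    p <- if (m$strand == "+") gpos[cds_pos] else
      rev(gpos)[cds_pos]
    ref <- base_at(m, p)
    anc_rows[[length(anc_rows) + 1L]] <- data.frame(
      gene_id = ids[i], position = p, ref = ref, alt = other_base(ref),
      stringsAsFactors = FALSE)
  }
  ancestral_variants <- if (length(anc_rows)) do.call(rbind, anc_rows) else
    data.frame(gene_id = character(), position = integer(),
               ref = character(), alt = character(), stringsAsFactors = FALSE)

  ## 3. per-line genomic mutations --------------------------------------
  ancestors <- sprintf("A%02d", seq_len(config$n_ancestors))
  line_ids <- unlist(lapply(ancestors, function(a)
    sprintf("%s_L%02d", a, seq_len(config$n_lines_per_ancestor))))
  line_anc <- stats::setNames(rep(ancestors,
                                  each = config$n_lines_per_ancestor),
                              line_ids)
  mut_rows <- list()
  for (l in line_ids) {
    n_mut <- stats::rpois(1L, config$mutation_rate_per_line)
    taken <- list()
    for (k in seq_len(n_mut)) {
      gi <- sample(config$n_proteins, 1L)
      m <- gene_models[[paste0(ids[gi], ".t1")]]
      avoid <- c(taken[[ids[gi]]],
                 ancestral_variants$position[
                   ancestral_variants$gene_id == ids[gi]])
      for (try in 1:20) {
        mv <- draw_mutation(m, config$indel_prob)
        span <- seq.int(mv$position, mv$position + nchar(mv$ref) - 1L)
        if (any(span %in% avoid)) next
        if (config$missense_only) {
          prot <- tryCatch(
            suppressWarnings(mutate_transcript(m, mv)$protein),
            error = function(e) "")
          if (nchar(prot) < nchar(families[[ids[gi]]]$query)) next
        }
        break
      }
      if (any(seq.int(mv$position, mv$position + nchar(mv$ref) - 1L) %in%
              avoid)) next
      taken[[ids[gi]]] <- c(taken[[ids[gi]]],
                            seq.int(mv$position,
                                    mv$position + nchar(mv$ref) - 1L))
      mut_rows[[length(mut_rows) + 1L]] <- cbind(
        data.frame(line_id = l, gene_id = ids[gi], stringsAsFactors = FALSE),
        mv)
    }
  }
  mutations <- if (length(mut_rows)) do.call(rbind, mut_rows) else
    data.frame(line_id = character(), gene_id = character(),
               position = integer(), ref = character(), alt = character(),
               stringsAsFactors = FALSE)

  ## 4. realize scores through the pipeline -----------------------------
  mut <- mutate_study(gene_models, mutations, ancestral_variants)
  support <- stats::setNames(lapply(ids, function(g)
    unname(families[[g]]$support)), paste0(ids, ".t1"))
  raw_scores <- score_variants(mut$variants, mut$queries, support, scoring)
  scores <- reduce_to_genes(raw_scores, scoring)

  ## 5. latent fitness and growth table ---------------------------------
  effect_of <- function(line) {
    s <- scores$score[scores$line_id == line & !is.na(scores$score)]
    switch(config$effect_model,
           uniform_per_mutation = config$effect_size * length(s),
           score_linked = config$effect_size * sum(s),
           deleterious_linked =
             config$effect_size * sum(s[s < config$effect_cutoff]))
  }
  fitness <- vapply(line_ids, effect_of, numeric(1))
  block_eff <- stats::rnorm(config$n_blocks, 0, config$block_sd)
  grow_rows <- function(line, anc, role, latent) {
    data.frame(line_id = line, role = role, ancestor_id = anc,
               environment = "E1", block = seq_len(config$n_blocks),
               replicate = seq_len(config$n_blocks),
               growth_rate = config$base_growth + latent + block_eff +
                 stats::rnorm(config$n_blocks, 0, config$replicate_sd),
               stringsAsFactors = FALSE)
  }
  growth <- do.call(rbind, c(
    lapply(line_ids, function(l)
      grow_rows(l, line_anc[[l]], "ma", fitness[[l]])),
    lapply(ancestors, function(a)
      do.call(rbind, lapply(seq_len(config$n_controls_per_ancestor),
                            function(j)
                              grow_rows(sprintf("%s_c%02d", a, j), a,
                                        "control", 0))))))
  rownames(growth) <- NULL

  structure(list(config = config, gene_models = gene_models,
                 families = families, queries = mut$queries,
                 references = mut$references,
                 variants = mut$variants,
                 mutations = mutations,
                 ancestral_variants = ancestral_variants,
                 growth = growth, scores = scores,
                 line_ancestors = line_anc,
                 truth = list(line_fitness = fitness,
                              block_effects = block_eff)),
            class = "ma_study")
}

#' @export
print.ma_study <- function(x, ...) {
  cat("<ma_study> ", x$config$n_proteins, " proteins, ",
      length(x$line_ancestors), " MA lines (",
      x$config$n_ancestors, " ancestors), ",
      nrow(x$mutations), " genomic mutations, effect model '",
      x$config$effect_model, "'\n", sep = "")
  invisible(x)
}

#' Write a synthetic study to disk in the standard input formats
#'
#' Emits gene models, mutation and ancestral-variant tables, the growth
#' table, and per-protein FASTA files (query and supporting sets) so
#' the full pipeline can be exercised from files.
#'
#' @param study An `ma_study` from [simulate_ma_study()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the written file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    gene_models = file.path(dir, "gene_models.tsv"),
    mutations = file.path(dir, "mutations.tsv"),
    ancestral = file.path(dir, "ancestral_variants.tsv"),
    growth = file.path(dir, "growth.tsv"),
    queries = file.path(dir, "queries.fasta"),
    support = file.path(dir, "support.fasta"))
  write_gene_models(study$gene_models, paths["gene_models"])
  write_tsv(study$mutations, paths["mutations"])
  write_tsv(study$ancestral_variants, paths["ancestral"])
  write_tsv(study$growth, paths["growth"])
  write_fasta(study$queries, paths["queries"])
  all_support <- unlist(lapply(names(study$families), function(g)
    study$families[[g]]$support))
  write_fasta(all_support, paths["support"])
  invisible(paths)
}
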