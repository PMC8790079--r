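#' Assemble per-line model data from a study
#'
#' Convenience wrapper joining the per-line summary statistics
#' (computed from a gene-level score table at a given threshold) with
#' relative fitness estimated from the growth table. This is the input
#' expected by [fit_origin_lm()], [fit_origin_mixed()], and
#' [threshold_sweep()].
#'
#' @param scores Gene-level score table (see [reduce_to_genes()]).
#' @param growth Growth table.
#' @param threshold Deleterious cutoff (default -2.5).
#' @param essential_genes Optional essential-gene id vector.
#' @param response_mode Passed to [relative_fitness()].
#' @param exclusions Optional exclusion table applied to the lines.
#' @return Data frame with one row per MA line: summary statistics plus
#'   `relative_fitness` and `ancestor_id`.
#' @export
study_line_data <- function(scores, growth, threshold = -2.5,
                            essential_genes = NULL,
                            response_mode = "signed", exclusions = NULL) {
  fitness <- relative_fitness(growth, response_mode = response_mode)
  fitness <- apply_exclusions(fitness, exclusions)
  summaries <- summarize_lines(
    scores, essential_genes = essential_genes, threshold = threshold,
    line_ids = fitness$line_id,
    ancestors = stats::setNames(fitness$ancestor_id, fitness$line_id))
  merged <- merge(summaries, fitness, by = c("line_id", "ancestor_id"),
                  sort = FALSE)
  merged
}

#' Run the full analysis pipeline
#'
#' Executes the standard stages in order — simulate (optional), mutate,
#' score, aggregate, fit, and optionally sweep — writing each stage's
#' artifact as a TSV into `out_dir` and returning a manifest of every
#' file with its content hash. A stage failure stops the run and leaves
#' prior artifacts intact.
#'
#' The configuration is a named list (or path to a YAML file) with
#' elements:
#' \describe{
#'   \item{seed}{integer; mandatory when `simulate` is present}
#'   \item{simulate}{optional list of [sim_config()] arguments; when
#'     absent, `paths` must name the input files}
#'   \item{paths}{optional list with `gene_models`, `mutations`,
#'     `ancestral_variants`, `growth`, `queries`, `support`,
#'     `essential_genes`, `exclusions`}
#'   \item{threshold}{deleterious cutoff (default -2.5)}
#'   \item{response_mode}{`"signed"` (default) or `"absolute"`}
#'   \item{predictors}{predictor sets to fit (default `psi_tot`,
#'     `psi_del`, `psi_abs`, `sigma_tot`)}
#'   \item{mixed_group}{optional grouping column (e.g. `ancestor_id`)
#'     for random-slope fits}
#'   \item{sweep}{optional list with `from`, `to`, `by` for a
#'     threshold sweep}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @param out_dir Output directory (default `"maprovean_run"`).
#' @return List with `manifest` (data frame of file, md5), `line_data`,
#'   `selection` (AICc table), and `sweep` (or `NULL`), invisibly.
#' @export
run_pipeline <- function(config, out_dir = "maprovean_run") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  threshold <- config$threshold %||% -2.5
  scoring <- do.call(scoring_config, c(config$scoring, list()))
  scoring$threshold <- threshold

  ## validate the configuration before any stage executes
  if (is.null(config$paths$essential_genes) &&
      any(grepl("_ess$", unlist(config$predictors %||% character()))))
    stop("config error: *_ess predictors requested without an ",
         "essential-gene list")

  if (!is.null(config$simulate)) {
    if (is.null(config$seed)) stop("config error: simulate requires a seed")
    study <- simulate_ma_study(
      do.call(sim_config, c(list(seed = config$seed), config$simulate)),
      scoring = scoring)
    gene_models <- study$gene_models
    mutations <- study$mutations
    ancestral <- study$ancestral_variants
    growth <- study$growth
    support <- stats::setNames(
      lapply(names(study$families), function(g) unname(study$families[[g]]$support)),
      vapply(names(study$families), function(g) paste0(g, ".t1"), character(1)))
    write_study(study, out_dir)
  } else {
    p <- config$paths
    needed <- c("gene_models", "mutations", "growth", "support")
    miss <- needed[!vapply(needed, function(k)
      !is.null(p[[k]]) && file.exists(p[[k]]), logical(1))]
    if (length(miss))
      stop("config error: missing input path(s): ", paste(miss, collapse = ", "))
    gene_models <- read_gene_models(p$gene_models)
    mutations <- read_mutation_table(p$mutations)
    ancestral <- if (!is.null(p$ancestral_variants))
      read_mutation_table_like(p$ancestral_variants) else NULL
    growth <- read_growth_table(p$growth)
    sup_all <- read_fasta(p$support)
    ## support sequence ids are "<protein_id>_h<i>"
    support <- split(unname(sup_all), sub("_h[0-9]+$", "", names(sup_all)))
    support <- stats::setNames(support, paste0(names(support), ".t1"))
  }
  essential <- if (!is.null(config$paths$essential_genes))
    read_essential_genes(config$paths$essential_genes) else NULL
  exclusions <- if (!is.null(config$paths$exclusions))
    read_exclusion_table(config$paths$exclusions) else NULL

  ## mutate ---------------------------------------------------------------
  mut <- mutate_study(gene_models, mutations, ancestral)
  write_tsv(mut$variants, file.path(out_dir, "variants.tsv"))
  write_fasta(mut$queries, file.path(out_dir, "query_proteins.fasta"))

  ## score ----------------------------------------------------------------
  raw_scores <- score_variants(mut$variants, mut$queries, support, scoring)
  scores <- reduce_to_genes(raw_scores, scoring)
  write_tsv(scores, file.path(out_dir, "scores.tsv"))

  ## aggregate ------------------------------------------------------------
  line_data <- study_line_data(scores, growth, threshold = threshold,
                               essential_genes = essential,
                               response_mode = config$response_mode %||% "signed",
                               exclusions = exclusions)
  write_tsv(line_data, file.path(out_dir, "lines.tsv"))

  ## fit ------------------------------------------------------------------
  predictors <- config$predictors %||%
    list("psi_tot", "psi_del", "psi_abs", "sigma_tot")
  fits <- list()
  for (pr in predictors) {
    pr <- unlist(pr)
    dat <- line_data[stats::complete.cases(line_data[c("relative_fitness", pr)]), ]
    fit <- tryCatch({
      if (!is.null(config$mixed_group) && length(pr) == 1L)
        fit_origin_mixed(dat, pr, group = config$mixed_group)
      else fit_origin_lm(dat, pr)
    }, error = function(e) {
      message("fit '", paste(pr, collapse = "+"), "' failed: ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(fit)) fits[[paste(pr, collapse = "+")]] <- fit
  }
  if (!length(fits)) stop("stage 'fit' failed: no model could be fitted")
  selection <- model_selection_table(fits)
  write_tsv(selection, file.path(out_dir, "models.tsv"))

  ## sweep ----------------------------------------------------------------
  sweep <- NULL
  if (!is.null(config$sweep)) {
    grid <- seq(config$sweep$from %||% -10, config$sweep$to %||% 0,
                by = config$sweep$by %||% 0.25)
    sweep <- threshold_sweep(scores, line_data, grid = grid)
    write_tsv(data.frame(threshold = sweep$thresholds, AICc = sweep$AICc,
                         proportion_deleterious = sweep$proportion_deleterious),
              file.path(out_dir, "sweep.tsv"))
  }

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(manifest = manifest, line_data = line_data,
                 selection = selection, sweep = sweep))
}

## ancestral-variant tables share the mutation-table layout minus line_id
read_mutation_table_like <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "position", "ref", "alt"),
                         "ancestral variant")
  df$position <- validate_coordinate(df$position, "position")
  df$ref <- toupper(df$ref); df$alt <- toupper(df$alt)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
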