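#' Relative fitness of MA lines
#'
#' Computes one response value per MA line: the line's block-adjusted
#' mean growth rate minus the block-adjusted mean of its matched
#' control (ancestor) lines. Lines are matched to controls sharing
#' their grouping factors (ancestor and, when present, environment).
#' Block effects are removed with a fixed block factor, so adding a
#' constant offset to every measurement of one block leaves all
#' relative fitness values unchanged. Controls have relative fitness 0
#' by construction (their mean defines the baseline).
#'
#' @param growth Growth table (see [read_growth_table()]).
#' @param response_mode `"signed"` or `"absolute"`; absolute mode
#'   returns `|value|`, used for data sets without a directional mean
#'   fitness change.
#' @param match_cols Grouping factors used to match MA lines to
#'   controls; defaults to `ancestor_id` plus `environment` when that
#'   column exists.
#' @param no_controls When `TRUE`, strata without control rows are
#'   allowed and the stratum's baseline is 0 (for the sensitivity
#'   analysis that removes the fixed intercept downstream).
#' @return Data frame with `line_id`, `ancestor_id`, `relative_fitness`.
#' @export
relative_fitness <- function(growth, response_mode = c("signed", "absolute"),
                             match_cols = NULL, no_controls = FALSE) {
  response_mode <- match.arg(response_mode)
  if (is.null(match_cols))
    match_cols <- intersect(c("ancestor_id", "environment"), names(growth))
  strata <- interaction(growth[match_cols], drop = TRUE)
  out <- list()
  for (s in levels(strata)) {
    g <- growth[strata == s, , drop = FALSE]
    has_controls <- any(g$role == "control")
    if (!has_controls && !no_controls)
      stop("stratum '", s, "' has MA lines but no matched control rows ",
           "(set no_controls = TRUE to allow)")
    lines_f <- factor(g$line_id)
    blocks_f <- factor(g$block)
    if (nlevels(blocks_f) > 1L) {
      ## hand-built indicator design: avoids contrast machinery so
      ## strata with a single line still fit
      X <- vapply(levels(lines_f), function(l) as.numeric(g$line_id == l),
                  numeric(nrow(g)))
      B <- vapply(levels(blocks_f)[-1L], function(b) as.numeric(g$block == b),
                  numeric(nrow(g)))
      cf <- stats::lm.fit(cbind(X, B), g$growth_rate)$coefficients
      eff <- cf[levels(lines_f)]
    } else {
      eff <- tapply(g$growth_rate, g$line_id, mean)
    }
    ctl_lines <- unique(g$line_id[g$role == "control"])
    baseline <- if (has_controls) mean(eff[ctl_lines]) else 0
    ma_lines <- unique(g$line_id[g$role == "ma"])
    val <- unname(eff[ma_lines]) - baseline
    if (response_mode == "absolute") val <- abs(val)
    out[[s]] <- data.frame(
      line_id = ma_lines,
      ancestor_id = g$ancestor_id[match(ma_lines, g$line_id)],
      relative_fitness = val, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Intraclass correlation of growth measurements
#'
#' One-way random-effects decomposition of growth rate by line
#' identity: `icc = var_line / (var_line + var_resid)`, with the
#' percentage of variance attributable to line identity.
#'
#' @param growth Growth table with replicated measurements.
#' @param value_col Measurement column (default `growth_rate`).
#' @param group_col Grouping column (default `line_id`).
#' @return List with `icc`, `pct_variance_line`, `var_line`,
#'   `var_resid`.
#' @export
icc_and_variance <- function(growth, value_col = "growth_rate",
                             group_col = "line_id") {
  g <- factor(growth[[group_col]])
  y <- growth[[value_col]]
  reps <- table(g)
  if (length(reps) < 2L || all(reps < 2L))
    stop("intraclass correlation needs at least two groups with replicates")
  fit <- lme4::lmer(y ~ 1 + (1 | g), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_line <- vc$vcov[vc$grp == "g"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  icc <- var_line / (var_line + var_resid)
  list(icc = icc, pct_variance_line = 100 * icc,
       var_line = var_line, var_resid = var_resid)
}

aicc_from <- function(logLik, K, n) {
  aic <- -2 * logLik + 2 * K
  aic + 2 * K * (K + 1) / (n - K - 1)
}

new_ma_fit <- function(fit, predictors, response, data, name, singular = FALSE) {
  ll <- stats::logLik(fit)
  K <- attr(ll, "df")
  n <- length(stats::residuals(fit))
  structure(list(
    model_name = name, predictors = predictors, response = response,
    coefficients = if (inherits(fit, "merMod")) lme4::fixef(fit)
                   else stats::coef(fit),
    log_likelihood = as.numeric(ll), K = K, n = n,
    AIC = -2 * as.numeric(ll) + 2 * K,
    AICc = aicc_from(as.numeric(ll), K, n),
    singular = singular, fit = fit, data = data), class = "ma_fit")
}

#' Through-origin linear fitness model
#'
#' Least-squares fit of relative fitness on one or more per-line
#' predictors with the intercept fixed at zero: the ancestor, carrying
#' no new mutations, has relative fitness 0 by construction, so the
#' regression is forced through the origin. Setting
#' `fixed_origin = FALSE` refits with a free intercept (the
#' no-controls sensitivity analysis); the two paths are distinct
#' models, not reparameterizations.
#'
#' @param data Data frame holding the response and predictors per line.
#' @param predictors Character vector of predictor column names.
#' @param response Response column (default `relative_fitness`).
#' @param covariates Optional extra predictor columns (e.g.
#'   `relative_genome_size`).
#' @param fixed_origin Fix the intercept at zero (default `TRUE`).
#' @param name Model label for selection tables; defaults to the
#'   predictor names.
#' @return An object of class `ma_fit`.
#' @export
fit_origin_lm <- function(data, predictors, response = "relative_fitness",
                          covariates = character(), fixed_origin = TRUE,
                          name = NULL) {
  terms <- c(predictors, covariates)
  missing <- setdiff(c(terms, response), names(data))
  if (length(missing))
    stop("column(s) not in data: ", paste(missing, collapse = ", "))
  for (p in terms)
    if (all(data[[p]] == 0))
      stop("predictor '", p, "' is identically zero; slope unidentifiable")
  rhs <- paste(c(if (fixed_origin) "0", terms), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = data)
  obj <- new_ma_fit(fit, terms, response, data,
                    name = if (is.null(name)) paste(predictors, collapse = "+")
                           else name)
  obj$coefficients <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  obj$p_values <- sm[, "Pr(>|t|)"]
  obj
}

#' Through-origin mixed model with a random slope
#'
#' Fits relative fitness on one predictor with no intercept, a fixed
#' overall slope, and per-group random slope deviations (used when MA
#' lines derive from several ancestral backgrounds). Estimation is by
#' maximum likelihood, not REML, so log-likelihoods are comparable
#' across fixed-effect structures in AICc tables. A singular fit
#' (random-slope variance estimated at the boundary) is flagged, not
#' silently accepted.
#'
#' @param data Data frame with response, predictor, and grouping
#'   columns.
#' @param predictor Predictor column name.
#' @param group Grouping column name (ancestral background).
#' @param response Response column.
#' @param covariates Optional fixed covariate columns.
#' @param fixed_origin Fix the intercept at zero (default `TRUE`).
#' @param name Model label.
#' @return An object of class `ma_fit` with a `singular` flag.
#' @export
fit_origin_mixed <- function(data, predictor, group,
                             response = "relative_fitness",
                             covariates = character(), fixed_origin = TRUE,
                             name = NULL) {
  if (length(unique(data[[group]])) < 2L)
    stop("random-slope model needs at least two groups")
  if (all(data[[predictor]] == 0))
    stop("predictor '", predictor, "' is identically zero")
  rhs <- paste(c(if (fixed_origin) "0", predictor, covariates,
                 paste0("(0 + ", predictor, " | ", group, ")")),
               collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- lme4::lmer(fml, data = data, REML = FALSE)
  singular <- lme4::isSingular(fit)
  if (singular)
    message("random-slope variance estimated at the boundary (singular fit)")
  obj <- new_ma_fit(fit, c(predictor, covariates), response, data,
                    name = if (is.null(name)) predictor else name,
                    singular = singular)
  sm <- stats::coef(summary(fit))
  obj$p_values <- 2 * stats::pnorm(-abs(sm[, "t value"]))
  obj
}

#' @export
print.ma_fit <- function(x, ...) {
  cat("<ma_fit> ", x$model_name, ": ", x$response, " ~ ",
      paste(x$predictors, collapse = " + "),
      " (n = ", x$n, ", K = ", x$K, ")\n", sep = "")
  cat("  coefficients:\n")
  print(round(x$coefficients, 6))
  cat("  logLik ", format(x$log_likelihood, digits = 6),
      ",  AICc ", format(x$AICc, digits = 6),
      if (x$singular) ",  SINGULAR random effect", "\n", sep = "")
  invisible(x)
}

#' @export
summary.ma_fit <- function(object, ...) summary(object$fit, ...)

#' @export
coef.ma_fit <- function(object, ...) object$coefficients

#' @export
predict.ma_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  if (inherits(object$fit, "merMod"))
    stats::predict(object$fit, newdata = newdata, re.form = NA, ...)
  else stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.ma_fit <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
logLik.ma_fit <- function(object, ...) stats::logLik(object$fit)

#' Model selection table ranked by AICc
#'
#' Ranks fitted models by the small-sample corrected AIC,
#' `AICc = -2 lnL + 2K + 2K(K+1)/(n - K - 1)`, where `K` counts every
#' estimated parameter (coefficients and variance components). All
#' fits must be on the same response data (equal `n`).
#'
#' @param fits List of `ma_fit` objects.
#' @return Data frame with one row per model, ranked ascending by
#'   AICc, with `delta_AICc` relative to the best model.
#' @export
model_selection_table <- function(fits) {
  stopifnot(length(fits) >= 1L)
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1L)
    stop("fits are on different data sizes: ", paste(ns, collapse = ", "))
  tab <- data.frame(
    model = vapply(fits, function(f) f$model_name, character(1)),
    K = vapply(fits, function(f) f$K, numeric(1)),
    logLik = vapply(fits, function(f) f$log_likelihood, numeric(1)),
    AICc = vapply(fits, function(f) f$AICc, numeric(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AICc), , drop = FALSE]
  tab$delta_AICc <- tab$AICc - tab$AICc[1L]
  rownames(tab) <- NULL
  tab
}

#' Sweep the deleterious threshold
#'
#' Recomputes the per-line deleterious count at each cutoff on a grid,
#' refits the through-origin fitness model, and records the AICc and
#' the pooled proportion of mutant proteins classified deleterious.
#' Cutoffs where every line's count is zero are recorded as undefined
#' (`NA` AICc), not fitted.
#'
#' @param scores Score table with `line_id` and `score` (gene-level).
#' @param fitness Per-line data frame with `line_id` and the response
#'   column.
#' @param grid Numeric vector of cutoffs (default -10 to 0 by 0.25).
#' @param response Response column in `fitness`.
#' @param group Optional grouping column in `fitness` for a
#'   random-slope mixed model instead of the plain lm.
#' @param covariates Optional covariate columns in `fitness`.
#' @return An object of class `ma_sweep`: list with `thresholds`,
#'   `AICc`, `proportion_deleterious`, `best_threshold`.
#' @export
threshold_sweep <- function(scores, fitness, grid = seq(-10, 0, by = 0.25),
                            response = "relative_fitness", group = NULL,
                            covariates = character()) {
  if (length(grid) == 0L) stop("empty threshold grid")
  grid <- sort(grid)
  sc <- scores[!is.na(scores$score), , drop = FALSE]
  aicc <- prop <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    cutoff <- grid[i]
    psi_del <- vapply(fitness$line_id, function(l)
      sum(sc$score[sc$line_id == l] < cutoff), numeric(1))
    prop[i] <- mean(sc$score < cutoff)
    if (all(psi_del == 0)) next
    dat <- fitness
    dat$psi_del <- psi_del
    fit <- tryCatch({
      if (is.null(group))
        fit_origin_lm(dat, "psi_del", response = response,
                      covariates = covariates)
      else
        fit_origin_mixed(dat, "psi_del", group = group, response = response,
                         covariates = covariates)
    }, error = function(e) NULL)
    if (!is.null(fit)) aicc[i] <- fit$AICc
  }
  best <- if (all(is.na(aicc))) NA_real_ else grid[which.min(aicc)]
  structure(list(thresholds = grid, AICc = aicc,
                 proportion_deleterious = prop, best_threshold = best),
            class = "ma_sweep")
}

#' @export
print.ma_sweep <- function(x, ...) {
  cat("<ma_sweep> ", length(x$thresholds), " cutoffs in [",
      min(x$thresholds), ", ", max(x$thresholds), "], best AICc at ",
      x$best_threshold, "\n", sep = "")
  invisible(x)
}

#' @export
plot.ma_sweep <- function(x, ...) {
  op <- graphics::par(mar = c(4, 4, 1, 4))
  on.exit(graphics::par(op))
  plot(x$thresholds, x$AICc, type = "l", xlab = "deleterious threshold",
       ylab = "AICc", ...)
  graphics::par(new = TRUE)
  plot(x$thresholds, x$proportion_deleterious, type = "l", lty = 2,
       axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4)
  graphics::mtext("proportion deleterious", side = 4, line = 2.5)
  invisible(x)
}
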