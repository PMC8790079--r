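#' Deleterious-classification contingency test
#'
#' Compares how often new MA mutations versus pre-existing ancestral
#' variants are classified deleterious at a common threshold, using a
#' two-sided Fisher exact test on the 2x2 table
#' (rows: new / ancestral; columns: deleterious / neutral). Ancestral
#' variants have been screened by natural selection, so under reference
#' bias they are expected to score less deleterious than new mutations.
#'
#' @param new_scores,ancestral_scores Numeric score vectors (unscored
#'   `NA`s are dropped).
#' @param threshold Deleterious cutoff (default -2.5).
#' @return List with `table` (2x2 matrix), `p_value`, `odds_ratio`.
#' @export
deleterious_contingency <- function(new_scores, ancestral_scores,
                                    threshold = -2.5) {
  new_scores <- new_scores[!is.na(new_scores)]
  ancestral_scores <- ancestral_scores[!is.na(ancestral_scores)]
  tab <- rbind(new = c(deleterious = sum(new_scores < threshold),
                       neutral = sum(new_scores >= threshold)),
               ancestral = c(deleterious = sum(ancestral_scores < threshold),
                             neutral = sum(ancestral_scores >= threshold)))
  if (any(rowSums(tab) == 0L))
    stop("empty group: both score vectors must be non-empty")
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, p_value = ft$p.value,
       odds_ratio = unname(ft$estimate))
}

## Exact two-sided rank-sum p-value by enumeration of all assignments
## of the pooled (mid-)ranks to the first group. Handles ties through
## average ranks; p = P(|W - E[W]| >= |w_obs - E[W]|).
ranksum_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(nx + ny, nx)
  w_all <- colSums(matrix(r[combos], nrow = nx))
  ew <- nx * (nx + ny + 1) / 2
  eps <- 1e-9
  mean(abs(w_all - ew) >= abs(w_obs - ew) - eps)
}

#' Rank-sum comparison of score distributions
#'
#' Two-sided Wilcoxon rank-sum test of new-mutation scores against
#' ancestral-variant scores. For combined sample sizes up to
#' `exact_limit` the p-value is computed by exact enumeration of rank
#' assignments (valid under ties via mid-ranks); larger samples use
#' the tie-corrected normal approximation.
#'
#' @param new_scores,ancestral_scores Numeric vectors (`NA`s dropped).
#' @param exact_limit Combined size at or below which enumeration is
#'   used (default 20).
#' @return List with `p_value`, `statistic` (rank-sum W of the first
#'   group), and `method`.
#' @export
score_ranksum <- function(new_scores, ancestral_scores, exact_limit = 20L) {
  x <- new_scores[!is.na(new_scores)]
  y <- ancestral_scores[!is.na(ancestral_scores)]
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  w <- sum(rank(c(x, y))[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  if (length(x) + length(y) <= exact_limit) {
    p <- ranksum_exact_p(x, y)
    method <- "exact enumeration"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    method <- "tie-corrected normal approximation"
  }
  list(p_value = p, statistic = w, method = method)
}

#' Bootstrap confidence interval for a median score
#'
#' Percentile bootstrap of the sample median, seeded for
#' reproducibility.
#'
#' @param scores Numeric vector (at least 2 values).
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param conf Confidence level (default 0.95).
#' @return List with `median`, `lower`, `upper`, `conf`.
#' @export
median_ci <- function(scores, n_boot = 10000L, seed = NULL, conf = 0.95) {
  scores <- scores[!is.na(scores)]
  stopifnot(length(scores) >= 2L)
  if (!is.null(seed)) set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i)
    stats::median(sample(scores, replace = TRUE)), numeric(1))
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(median = stats::median(scores), lower = qs[1], upper = qs[2],
       conf = conf)
}

#' Grouped logistic model of deleterious status
#'
#' Logistic regression of deleterious classification on variant origin
#' (new mutation vs ancestral variant) with a random intercept for
#' ancestral background. When the random-effect fit is singular or
#' fails, falls back (flagged) to a fixed effect per background.
#' Complete separation is flagged and the reported p-value comes from
#' the profile (likelihood-ratio) test, which remains finite under
#' separation.
#'
#' @param deleterious Logical vector: classified deleterious?
#' @param origin Factor/character: `"new"` or `"ancestral"` per
#'   variant.
#' @param ancestor Ancestral background per variant (at least 2
#'   levels).
#' @return List with `coefficient` (log-odds of deleterious for new vs
#'   ancestral), `p_value`, `per_group_logodds`, `method`, `singular`,
#'   `separation`.
#' @export
grouped_deleterious_model <- function(deleterious, origin, ancestor) {
  stopifnot(length(deleterious) == length(origin),
            length(origin) == length(ancestor))
  origin <- factor(origin, levels = c("ancestral", "new"))
  ancestor <- factor(ancestor)
  if (nlevels(ancestor) < 2L)
    stop("need at least two ancestral backgrounds")
  dat <- data.frame(del = as.logical(deleterious), origin = origin,
                    anc = ancestor)

  per_group <- vapply(levels(ancestor), function(a) {
    d <- dat[dat$anc == a, , drop = FALSE]
    p_new <- mean(d$del[d$origin == "new"])
    p_anc <- mean(d$del[d$origin == "ancestral"])
    log(p_new / (1 - p_new)) - log(p_anc / (1 - p_anc))
  }, numeric(1))

  singular <- FALSE
  fit <- tryCatch({
    m <- lme4::glmer(del ~ origin + (1 | anc), data = dat, family = stats::binomial)
    singular <- lme4::isSingular(m)
    if (singular) NULL else m
  }, error = function(e) NULL, warning = function(w) NULL)

  if (is.null(fit)) {
    m <- stats::glm(del ~ origin + anc, data = dat, family = stats::binomial)
    beta <- stats::coef(m)["originnew"]
    separation <- is.na(beta) || abs(beta) > 10
    lrt <- stats::drop1(m, scope = ~origin, test = "Chisq")
    p <- lrt[["Pr(>Chi)"]][2L]
    method <- if (singular) "fixed-effect fallback (singular random effect)"
              else "fixed-effect fallback"
  } else {
    beta <- lme4::fixef(fit)["originnew"]
    separation <- abs(beta) > 10
    if (separation) {
      ## profile-based p stays finite when the Wald z degenerates
      m0 <- lme4::glmer(del ~ 1 + (1 | anc), data = dat, family = stats::binomial)
      p <- stats::anova(fit, m0)[["Pr(>Chisq)"]][2L]
    } else {
      sm <- stats::coef(summary(fit))
      p <- sm["originnew", "Pr(>|z|)"]
    }
    method <- "random-intercept logistic"
  }
  list(coefficient = unname(beta), p_value = p,
       per_group_logodds = per_group, method = method,
       singular = singular, separation = separation)
}
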