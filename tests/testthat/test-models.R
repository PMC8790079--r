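make_growth <- function(lines, ctl = "C1", blocks = 2, reps_per_block = 1,
                        line_means = NULL, ctl_mean = 1, sd = 0,
                        block_offsets = rep(0, blocks)) {
  if (is.null(line_means)) line_means <- rep(1, length(lines))
  rows <- list()
  for (i in seq_along(lines)) for (b in seq_len(blocks))
    for (r in seq_len(reps_per_block))
      rows[[length(rows) + 1]] <- data.frame(
        line_id = lines[i], role = "ma", ancestor_id = "A1",
        block = b, replicate = r,
        growth_rate = line_means[i] + block_offsets[b] + rnorm(1, 0, sd))
  for (b in seq_len(blocks)) for (r in seq_len(reps_per_block))
    rows[[length(rows) + 1]] <- data.frame(
      line_id = ctl, role = "control", ancestor_id = "A1",
      block = b, replicate = r,
      growth_rate = ctl_mean + block_offsets[b] + rnorm(1, 0, sd))
  do.call(rbind, rows)
}

test_that("relative fitness is zero when line and control coincide", {
  g <- make_growth("L1", line_means = 1, ctl_mean = 1)
  rf <- relative_fitness(g)
  expect_equal(rf$relative_fitness, 0, tolerance = 1e-12)
})

test_that("a constant block offset leaves relative fitness unchanged", {
  set.seed(51)
  base <- make_growth(c("L1", "L2", "L3"), line_means = c(0.9, 1.0, 1.1),
                      sd = 0.05)
  shifted <- base
  shifted$growth_rate[shifted$block == 2] <-
    shifted$growth_rate[shifted$block == 2] + 0.37
  expect_equal(relative_fitness(base)$relative_fitness,
               relative_fitness(shifted)$relative_fitness,
               tolerance = 1e-10)
})

test_that("single-measurement designs reduce to mean differences", {
  g <- rbind(
    data.frame(line_id = "L1", role = "ma", ancestor_id = "A1", block = 1,
               replicate = 1, growth_rate = 0.8),
    data.frame(line_id = c("C1", "C2"), role = "control", ancestor_id = "A1",
               block = 1, replicate = 1, growth_rate = c(1.0, 1.2)))
  expect_equal(relative_fitness(g)$relative_fitness, 0.8 - 1.1)
})

test_that("absolute response mode returns magnitudes", {
  g <- make_growth(c("L1", "L2"), line_means = c(0.8, 1.2))
  rf <- relative_fitness(g, response_mode = "absolute")
  expect_equal(sort(rf$relative_fitness), c(0.2, 0.2), tolerance = 1e-12)
})

test_that("an MA line without matched controls is an error unless allowed", {
  g <- make_growth("L1")
  g <- g[g$role == "ma", ]
  expect_error(relative_fitness(g), "no matched control")
  rf <- relative_fitness(g, no_controls = TRUE)
  expect_equal(nrow(rf), 1L)
})

test_that("icc is 1 for perfect repeatability and ~0 under the null", {
  g <- data.frame(line_id = rep(c("L1", "L2", "L3"), each = 4),
                  growth_rate = rep(c(0.8, 1.0, 1.2), each = 4))
  expect_equal(suppressWarnings(icc_and_variance(g))$icc, 1, tolerance = 1e-6)

  set.seed(61)
  g0 <- data.frame(line_id = rep(sprintf("L%02d", 1:30), each = 5),
                   growth_rate = rnorm(150))
  expect_lt(icc_and_variance(g0)$icc, 0.15)
})

test_that("icc matches the balanced ANOVA variance-components oracle", {
  set.seed(63)
  g <- data.frame(line_id = rep(sprintf("L%02d", 1:12), each = 6),
                  growth_rate = rep(rnorm(12, 1, 0.1), each = 6) +
                    rnorm(72, 0, 0.05))
  got <- icc_and_variance(g)$icc
  want <- oracle_icc_balanced(g$growth_rate, g$line_id)
  expect_equal(got, want, tolerance = 1e-4)
})

test_that("through-origin regression matches the closed form", {
  d <- data.frame(relative_fitness = c(-1, -2), x = c(1, 2))
  f <- suppressWarnings(fit_origin_lm(d, "x"))
  expect_equal(unname(coef(f)), -1)
  expect_equal(max(abs(residuals(f))), 0, tolerance = 1e-12)

  set.seed(71)
  d2 <- data.frame(relative_fitness = rnorm(40), x = rnorm(40))
  f2 <- fit_origin_lm(d2, "x")
  expect_equal(unname(coef(f2)),
               sum(d2$x * d2$relative_fitness) / sum(d2$x^2),
               tolerance = 1e-10)

  expect_error(fit_origin_lm(data.frame(relative_fitness = 1:3, x = 0),
                             "x"), "identically zero")
})

test_that("fixing the intercept is not the same as adding an origin point", {
  set.seed(73)
  d <- data.frame(relative_fitness = rnorm(20, -1), x = rpois(20, 3) + 1)
  fixed <- fit_origin_lm(d, "x")
  free_aug <- fit_origin_lm(rbind(d, data.frame(relative_fitness = 0, x = 0)),
                            "x", fixed_origin = FALSE)
  expect_equal(length(coef(fixed)), 1L)
  expect_equal(length(coef(free_aug)), 2L)
  expect_false(isTRUE(all.equal(unname(coef(fixed)),
                                unname(coef(free_aug)["x"]))))
})

test_that("multi-predictor origin fits support the del/non-del split", {
  set.seed(75)
  n <- 40
  d <- data.frame(psi_del = rpois(n, 2), psi_non_del = rpois(n, 3))
  d$relative_fitness <- -0.08 * d$psi_del - 0.03 * d$psi_non_del +
    rnorm(n, 0, 0.02)
  f <- fit_origin_lm(d, c("psi_del", "psi_non_del"))
  expect_equal(length(coef(f)), 2L)
  expect_lt(f$p_values["psi_non_del"], 0.01)
})

test_that("random-slope recovery: fixed slope near the generating value", {
  set.seed(77)
  groups <- sprintf("G%d", 1:6)
  slopes <- rnorm(6, -0.02, 0.005)
  d <- do.call(rbind, lapply(1:6, function(g)
    data.frame(group = groups[g], x = rpois(14, 4),
               relative_fitness = NA_real_)))
  d$relative_fitness <- slopes[match(d$group, groups)] * d$x +
    rnorm(nrow(d), 0, 0.01)
  f <- fit_origin_mixed(d, "x", group = "group")
  se <- sqrt(diag(as.matrix(vcov(f$fit))))[1]
  expect_lt(abs(unname(coef(f)) - (-0.02)), 3 * se + 0.005)
  expect_false(f$singular)
})

test_that("zero slope heterogeneity collapses toward the lm fit", {
  set.seed(79)
  d <- do.call(rbind, lapply(1:5, function(g)
    data.frame(group = paste0("G", g), x = rpois(12, 4))))
  d$relative_fitness <- -0.05 * d$x + rnorm(nrow(d), 0, 0.01)
  f_mixed <- suppressMessages(fit_origin_mixed(d, "x", group = "group"))
  f_lm <- fit_origin_lm(d, "x")
  expect_equal(unname(coef(f_mixed)), unname(coef(f_lm)), tolerance = 0.02)
  vc <- as.data.frame(lme4::VarCorr(f_mixed$fit))
  expect_lt(vc$vcov[1], 1e-4)
})

test_that("AICc follows the second-order formula and ranking rules", {
  ## K = 2, lnL = 0, n = 10: AIC = 4, AICc = 4 + 12/7
  fake <- structure(list(model_name = "fake", K = 2, n = 10,
                         log_likelihood = 0, AICc = NA), class = "ma_fit")
  aicc <- -2 * 0 + 2 * 2 + 2 * 2 * 3 / (10 - 2 - 1)
  expect_equal(aicc, 4 + 12 / 7)

  set.seed(81)
  d <- data.frame(relative_fitness = rnorm(12, 0, 0.001),
                  x = rpois(12, 3) + 1)
  d$y2 <- d$x + rnorm(12, 0, 0.5)
  f1 <- fit_origin_lm(d, "x")
  f2 <- fit_origin_lm(d, "y2")
  tab <- model_selection_table(list(f1, f2))
  expect_equal(tab$delta_AICc[1], 0)
  expect_true(all(diff(tab$AICc) >= 0))
  ## tiny residual variance gives large lnL, hence negative AICc
  expect_lt(tab$AICc[1], 0)
  expect_equal(f1$AICc, -2 * f1$log_likelihood + 2 * f1$K +
                 2 * f1$K * (f1$K + 1) / (f1$n - f1$K - 1))
  expect_gte(f1$AICc, f1$AIC)
})

test_that("model selection requires a common data size", {
  set.seed(83)
  d <- data.frame(relative_fitness = rnorm(20), x = rnorm(20))
  f1 <- fit_origin_lm(d, "x")
  f2 <- fit_origin_lm(d[1:15, ], "x")
  expect_error(model_selection_table(list(f1, f2)), "different data sizes")
})

test_that("AICc converges to AIC as n grows", {
  set.seed(85)
  d <- data.frame(relative_fitness = rnorm(1e6), x = rnorm(1e6))
  f <- fit_origin_lm(d, "x")
  expect_lt(f$AICc - f$AIC, 1e-3)
})

test_that("threshold sweep records undefined cutoffs and monotone proportions", {
  set.seed(87)
  scores <- score_rows("L1", c(-6, -3, -1))
  scores <- rbind(scores, score_rows("L2", c(-4, -0.5)),
                  score_rows("L3", c(-8, -2.6)))
  fitness <- data.frame(line_id = c("L1", "L2", "L3"),
                        relative_fitness = c(-0.3, -0.15, -0.35))
  sw <- threshold_sweep(scores, fitness, grid = seq(-10, 0, 1))
  expect_true(is.na(sw$AICc[1]))                     # below every score
  expect_equal(sw$proportion_deleterious[1], 0)
  expect_true(all(diff(sw$proportion_deleterious) >= 0))
  expect_true(all(sw$proportion_deleterious >= 0 &
                  sw$proportion_deleterious <= 1))
  expect_error(threshold_sweep(scores, fitness, grid = numeric(0)), "empty")
})
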