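cfg <- scoring_config()

test_that("scoring_config validates its invariants", {
  expect_error(scoring_config(gap_open = 1, gap_extend = 5), "gap_extend")
  expect_error(scoring_config(cluster_identity = 0), "cluster_identity")
  expect_error(scoring_config(max_clusters = 0), "max_clusters")
  expect_equal(cfg$threshold, -2.5)
  expect_equal(cfg$substitution_matrix["W", "W"], 11)
})

test_that("align_score reproduces self-scores and is symmetric", {
  ## MKWLV against itself: sum of diagonal BLOSUM62 entries 5+5+11+4+4
  expect_equal(align_score("MKWLV", "MKWLV", cfg), 29)
  set.seed(5)
  for (i in 1:10) {
    a <- random_seq(sample(3:12, 1)); b <- random_seq(sample(3:12, 1))
    expect_equal(align_score(a, b, cfg), align_score(b, a, cfg))
  }
  expect_error(align_score("MKX", "MK", cfg), "unknown residue")
  expect_error(align_score("", "MK", cfg), "empty")
})

test_that("align_score matches the brute-force DP oracle", {
  ## exhaustive over all pairs of 4-letter words of length <= 2, plus a
  ## random sample of longer pairs
  alpha <- c("A", "C", "D", "E")
  words <- c(alpha, apply(expand.grid(alpha, alpha), 1, paste, collapse = ""))
  for (a in words) for (b in words)
    expect_equal(align_score(a, b, cfg), oracle_align(a, b), tolerance = 1e-9)
  set.seed(7)
  for (i in 1:60) {
    a <- paste(sample(alpha, sample(3:8, 1), TRUE), collapse = "")
    b <- paste(sample(alpha, sample(3:8, 1), TRUE), collapse = "")
    expect_equal(align_score(a, b, cfg), oracle_align(a, b), tolerance = 1e-9)
  }
})

test_that("greedy clustering partitions by representative identity", {
  expect_equal(greedy_cluster(c("MKWLV", "MKWLV"), cfg), list(c(1L, 2L)))
  two <- greedy_cluster(c("MKWLV", "DEDED"), cfg)
  expect_equal(length(two), 2L)

  ## structured family with unambiguous identities: agree with an
  ## independent simulation of the greedy rule
  set.seed(13)
  for (rep in 1:5) {
    base <- random_seq(40)
    seqs <- vapply(c(0, 2, 4, 14, 16, 30), function(k) {
      s <- strsplit(base, "")[[1]]
      if (k > 0) {
        idx <- sample(40, k)
        s[idx] <- vapply(s[idx], function(a)
          sample(setdiff(aa_letters, a), 1), character(1))
      }
      paste(s, collapse = "")
    }, character(1))
    got <- greedy_cluster(seqs, cfg)
    want <- oracle_greedy(seqs, cfg$cluster_identity)
    expect_equal(lapply(got, sort), lapply(want, sort))
  }
})

test_that("top-cluster selection ranks by identity and caps the list", {
  base <- random_seq(30)
  near <- sub("^.", "W", base)   # one substitution away
  far <- random_seq(30)
  clusters <- list(1L, 2L)
  sel <- select_top_clusters(clusters, c(far, near), base, cfg)
  expect_equal(sel[[1]], 2L)

  many <- rep(list(0L), 31)
  for (i in 1:31) many[[i]] <- i
  sel <- select_top_clusters(many, rep(base, 31), base, cfg)
  expect_equal(length(sel), 30L)
  expect_equal(unlist(sel), 1:30)   # ties broken by input order
})

test_that("removing an unselected cluster leaves the score unchanged", {
  set.seed(17)
  base <- random_seq(30)
  support_near <- c(base, sub("^.", "A", sub("A", "S", base)))
  far <- random_seq(12)           # low identity, ranks last
  small_cfg <- scoring_config(max_clusters = 1)
  desc <- paste0(substr(base, 2, 2), "2",
                 if (substr(base, 2, 2) == "V") "W" else "V")
  s_with <- delta_score(base, desc, support = c(support_near, far),
                        config = small_cfg)
  s_without <- delta_score(base, desc, support = support_near,
                           config = small_cfg)
  skip_if(is.na(s_with$score))
  expect_equal(s_with$score, s_without$score)
})

test_that("delta_score closed form: support equal to the query", {
  ## one supporting copy of the query: score is the BLOSUM62 difference
  r <- delta_score("MKWLV", "W3A", support = "MKWLV", config = cfg)
  expect_equal(r$score, -14)
  expect_equal(r$classification, "deleterious")

  ## identical variant scores 0 and is neutral
  r0 <- delta_score("MKWLV", "MKWLV", support = c("MKWLV", "MKWLV"),
                    config = cfg)
  expect_equal(r0$score, 0)
  expect_equal(r0$classification, "neutral")

  ## N identical copies in one cluster: same closed form regardless of N
  for (n in c(1, 3, 7)) {
    rn <- delta_score("MKWLV", "K2R", support = rep("MKWLV", n), config = cfg)
    expect_equal(rn$score,
                 cfg$substitution_matrix["R", "K"] -
                   cfg$substitution_matrix["K", "K"])
  }
})

test_that("delta_score equals a straight-line reimplementation", {
  set.seed(19)
  for (rep in 1:8) {
    q <- random_seq(sample(15:25, 1))
    ## two unambiguous clusters: close copies of the query and of a
    ## shuffled remote sequence
    close_copies <- vapply(1:3, function(i) {
      s <- strsplit(q, "")[[1]]
      idx <- sample(length(s), 2)
      s[idx] <- vapply(s[idx], function(a)
        sample(setdiff(aa_letters, a), 1), character(1))
      paste(s, collapse = "")
    }, character(1))
    remote <- random_seq(nchar(q))
    support <- c(close_copies, remote)
    mutant <- random_edit(q)
    if (mutant == q || !nzchar(mutant)) next
    got <- delta_score(q, mutant, support = support, config = cfg)
    ss <- supporting_set(q, support, cfg)
    want <- oracle_delta(q, mutant,
                         lapply(ss$selected, function(cl) support[cl]))
    expect_equal(got$score, want, tolerance = 1e-9)
  }
})

test_that("delta_score is invariant to supporting-sequence order", {
  set.seed(23)
  q <- random_seq(20)
  support <- vapply(1:5, function(i) {
    s <- strsplit(q, "")[[1]]
    idx <- sample(20, i)           # increasing divergence, no length ties
    s[idx] <- vapply(s[idx], function(a)
      sample(setdiff(aa_letters, a), 1), character(1))
    paste(c(s, sample(aa_letters, i)), collapse = "")
  }, character(1))
  desc <- paste0(substr(q, 1, 1), "1",
                 if (substr(q, 1, 1) == "V") "W" else "V")
  s1 <- delta_score(q, desc, support = support, config = cfg)
  s2 <- delta_score(q, desc, support = rev(support), config = cfg)
  skip_if(is.na(s1$score) && is.na(s2$score))
  expect_equal(s1$score, s2$score)
})

test_that("unscorable variants carry the unscored flag, not a number", {
  r <- delta_score("MKWLV", "A1V", support = character(0), config = cfg)
  expect_true(is.na(r$score))
  expect_match(r$flags, "unscored")

  ## full truncation leaves an empty mutant
  r2 <- delta_score("MKWLV", "M1_V5del", support = "MKWLV", config = cfg)
  expect_true(is.na(r2$score))
  expect_match(r2$flags, "unscored")
})

test_that("diagnostic flags reflect cluster and support counts", {
  r <- delta_score("MKWLV", "W3A", support = "MKWLV", config = cfg)
  expect_match(r$flags, "few_clusters")
  expect_match(r$flags, "few_support")
  expect_equal(r$n_clusters, 1L)
  expect_equal(r$n_supporting, 1L)
})

test_that("classification is a pure threshold rule on the score", {
  st <- cached_study()
  sc <- st$scores[!is.na(st$scores$score), ]
  expect_equal(sc$classification == "deleterious", sc$score < -2.5)
  ## neutral examples either side of zero but above the cutoff
  expect_true(all(c(0.5, -0.2) >= -2.5))
})

test_that("gene_level_score takes the minimum over transcripts", {
  rows <- rbind(score_row("L1", "g1", -2.7, protein_id = "g1.t1"),
                score_row("L1", "g1", -1.0, protein_id = "g1.t2"))
  g <- gene_level_score(rows, cfg)
  expect_equal(g$score, -2.7)
  expect_equal(g$classification, "deleterious")

  one <- score_row("L1", "g1", 0.3)
  expect_equal(gene_level_score(one, cfg)$score, 0.3)

  both <- rbind(score_row("L1", "g1", 0.2), score_row("L1", "g1", -0.1))
  expect_equal(gene_level_score(both, cfg)$score, -0.1)
  expect_equal(gene_level_score(both, cfg)$classification, "neutral")

  unscored <- score_row("L1", "g1", NA_real_)
  expect_true(is.na(gene_level_score(unscored, cfg)$score))
})

test_that("variant-type summary partitions all scored results", {
  rows <- rbind(score_row("L1", "g1", -3, variant = "A2V"),
                score_row("L1", "g2", -1, variant = "A2V"),
                score_row("L1", "g3", -4, variant = "K3_K5del"),
                score_row("L1", "g4", 0.5, variant = "K3dup"),
                score_row("L1", "g5", -9, variant = "A2_K8delinsWW"),
                score_row("L2", "g6", NA_real_, variant = "A2V"))
  tab <- summarize_by_variant_type(rows)
  expect_equal(sum(tab$n), 5L)
  sub <- tab[tab$type == "single aa substitution", ]
  expect_equal(sub$n, 2L)
  expect_equal(sub$max_score, -1)
  expect_equal(sub$min_score, -3)
  expect_equal(tab$type[tab$n == 1 & tab$min_score == -9], "complex")
})

test_that("cluster/support QC report computes rounded percentages", {
  rows <- do.call(rbind, lapply(1:50, function(i)
    score_row("L1", paste0("g", i), -1,
              n_clusters = if (i <= 4) 10L else 30L,
              n_supporting = if (i <= 37) 20L else 60L)))
  rep <- cluster_support_report(rows)
  expect_equal(rep$n_proteins, 50L)
  expect_equal(rep$pct_few_clusters, 8)
  expect_equal(rep$pct_few_support, 74)
})
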