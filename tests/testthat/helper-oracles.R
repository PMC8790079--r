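## Independent brute-force oracles used to validate the package's
## implementations. These deliberately share no code with R/: plain
## dynamic-programming matrices, explicit enumeration, and closed-form
## estimators.

b62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

## Ends-free (overlap) affine-gap alignment score by explicit Gotoh DP.
## A gap of length k costs open + k * extend; terminal gaps are free on
## both sequences.
oracle_align <- function(a, b, open = 10, extend = 1, S = b62) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  H <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)   # gap in b (consuming a)
  F <- matrix(NEG, n + 1, m + 1)   # gap in a (consuming b)
  H[1, ] <- 0; H[, 1] <- 0         # free leading gaps
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i - 1, j] - (open + extend), E[i - 1, j] - extend)
      F[i, j] <- max(H[i, j - 1] - (open + extend), F[i, j - 1] - extend)
      M <- H[i - 1, j - 1] + S[av[i - 1], bv[j - 1]]
      H[i, j] <- max(M, E[i, j], F[i, j])
    }
  }
  max(H[n + 1, ], H[, m + 1])      # free trailing gaps
}

## Global affine-gap alignment with traceback, returning matches and
## alignment columns (for the identity definition used in clustering).
oracle_global_identity <- function(a, b, open = 10, extend = 1, S = b62) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  gap <- function(k) if (k == 0) 0 else -(open + k * extend)
  H <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  H[1, 1] <- 0
  for (i in 2:(n + 1)) { E[i, 1] <- gap(i - 1); H[i, 1] <- E[i, 1] }
  for (j in 2:(m + 1)) { F[1, j] <- gap(j - 1); H[1, j] <- F[1, j] }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i - 1, j] - (open + extend), E[i - 1, j] - extend)
      F[i, j] <- max(H[i, j - 1] - (open + extend), F[i, j - 1] - extend)
      M <- H[i - 1, j - 1] + S[av[i - 1], bv[j - 1]]
      H[i, j] <- max(M, E[i, j], F[i, j])
    }
  }
  ## traceback counting matches and columns
  i <- n + 1; j <- m + 1
  state <- c("H", "E", "F")[which.max(c(H[n + 1, m + 1], -Inf, -Inf))]
  matches <- 0L; cols <- 0L
  while (i > 1 || j > 1) {
    if (i > 1 && j > 1 &&
        abs(H[i, j] - (H[i - 1, j - 1] + S[av[i - 1], bv[j - 1]])) < 1e-9) {
      if (av[i - 1] == bv[j - 1]) matches <- matches + 1L
      cols <- cols + 1L; i <- i - 1; j <- j - 1
    } else if (i > 1 && abs(H[i, j] - E[i, j]) < 1e-9) {
      ## walk the whole gap in b
      k <- 1L
      while (abs(E[i, j] - (E[i - k, j] - k * extend)) < 1e-9 &&
             i - k > 1) k <- k + 1L
      cols <- cols + k; i <- i - k
    } else if (j > 1 && abs(H[i, j] - F[i, j]) < 1e-9) {
      k <- 1L
      while (abs(F[i, j] - (F[i, j - k] - k * extend)) < 1e-9 &&
             j - k > 1) k <- k + 1L
      cols <- cols + k; j <- j - k
    } else if (i > 1) { cols <- cols + 1L; i <- i - 1 }
    else { cols <- cols + 1L; j <- j - 1 }
  }
  list(identity = matches / cols, matches = matches, cols = cols)
}

## Straight-line delta score for a known cluster partition.
oracle_delta <- function(query, mutant, cluster_seqs, open = 10, extend = 1,
                         S = b62) {
  per_cluster <- vapply(cluster_seqs, function(cl) {
    mean(vapply(cl, function(s) oracle_align(mutant, s, open, extend, S),
                numeric(1))) -
      mean(vapply(cl, function(s) oracle_align(query, s, open, extend, S),
                  numeric(1)))
  }, numeric(1))
  mean(per_cluster)
}

## Independent simulation of the greedy clustering rule (sort by
## decreasing length, join first representative above the identity
## cutoff) using the oracle identity.
oracle_greedy <- function(sequences, cutoff) {
  ord <- order(-nchar(sequences))
  clusters <- list(); reps <- character()
  for (i in ord) {
    joined <- FALSE
    for (k in seq_along(clusters)) {
      if (oracle_global_identity(reps[k], sequences[i])$identity >= cutoff) {
        clusters[[k]] <- c(clusters[[k]], i); joined <- TRUE; break
      }
    }
    if (!joined) {
      clusters[[length(clusters) + 1L]] <- i
      reps[length(clusters)] <- sequences[i]
    }
  }
  clusters
}

## Exact two-sided Fisher p by hypergeometric enumeration over all 2x2
## tables with the observed margins.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1), numeric(1))
  obs <- probs[tab[1, 1] - lo + 1L]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

## Exact two-sided rank-sum p by enumeration of rank assignments.
oracle_ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  ew <- nx * (nx + ny + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  w_all <- colSums(matrix(r[combos], nrow = nx))
  mean(abs(w_all - ew) >= abs(w_obs - ew) - 1e-9)
}

## Balanced one-way ANOVA variance components.
oracle_icc_balanced <- function(values, groups) {
  k <- length(unique(groups))
  n_per <- length(values) / k
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  msb <- n_per * sum((means - gm)^2) / (k - 1)
  msw <- sum((values - means[as.character(groups)])^2) / (length(values) - k)
  var_g <- max((msb - msw) / n_per, 0)
  var_g / (var_g + msw)
}

## Random single-edit generator over the supported notation, built by
## direct string surgery (independent of diff/parse).
aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_seq <- function(n) paste(sample(aa_letters, n, replace = TRUE),
                                collapse = "")

random_edit <- function(query) {
  n <- nchar(query)
  type <- sample(c("sub", "del", "ins", "dup", "delins"), 1L)
  qa <- strsplit(query, "")[[1]]
  if (type == "sub") {
    p <- sample.int(n, 1L)
    qa[p] <- sample(setdiff(aa_letters, qa[p]), 1L)
    return(paste(qa, collapse = ""))
  }
  if (type == "del") {
    s <- sample.int(n, 1L); e <- min(n, s + sample(0:3, 1L))
    return(paste(qa[-(s:e)], collapse = ""))
  }
  if (type == "ins") {
    p <- sample.int(n, 1L)
    ins <- paste(sample(aa_letters, sample(1:3, 1L), TRUE), collapse = "")
    return(paste0(substr(query, 1, p), ins, substring(query, p + 1)))
  }
  if (type == "dup") {
    e <- sample.int(n, 1L); s <- max(1L, e - sample(0:2, 1L))
    return(paste0(substr(query, 1, e), substr(query, s, e),
                  substring(query, e + 1)))
  }
  s <- sample.int(n, 1L); e <- min(n, s + sample(0:3, 1L))
  rep <- paste(sample(aa_letters, sample(1:4, 1L), TRUE), collapse = "")
  paste0(substr(query, 1, s - 1L), rep, substring(query, e + 1))
}
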