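test_that("splice_cds concatenates exons and honours strand", {
  m <- gene_model("g", "t", "+", c(1, 9), c(5, 12), "ATGGCNNNTTGA")
  expect_equal(splice_cds(m), "ATGGCTTGA")

  plus <- demo_gene_model("+")
  minus <- demo_gene_model("-")
  expect_equal(splice_cds(plus), "ATGGCTTGGAAATGA")
  expect_equal(splice_cds(minus), splice_cds(plus))
})

test_that("zero-variant pipeline reproduces the reference transcript", {
  ## the generator designs the protein first; splicing + translation of
  ## the unmutated model must recover it exactly, on either strand
  set.seed(11)
  for (i in 1:20) {
    prot <- random_seq(sample(20:60, 1))
    m <- simulate_gene_model(prot, "g", "g.t1")
    expect_equal(translate_cds(splice_cds(m)), prot)
    expect_equal(mutate_transcript(m, NULL)$protein, prot)
  }
})

test_that("apply_genomic_variants edits jointly, high position first", {
  cds <- "ATGGCTTGA"
  expect_equal(apply_genomic_variants(
    cds, data.frame(position = 4, ref = "G", alt = "T")), "ATGTCTTGA")

  two <- data.frame(position = c(2, 6), ref = c("T", "T"), alt = c("A", "G"))
  expect_equal(apply_genomic_variants(cds, two), "AAGGCGTGA")

  del3 <- data.frame(position = 3, ref = "GGCT", alt = "G")
  expect_equal(nchar(apply_genomic_variants(cds, del3)), nchar(cds) - 3L)

  expect_equal(apply_genomic_variants(cds, NULL), cds)
  expect_equal(apply_genomic_variants(cds, del3[0, ]), cds)
})

test_that("apply_genomic_variants rejects overlaps and ref mismatches", {
  cds <- "ATGGCTTGA"
  overlap <- data.frame(position = c(3, 4), ref = c("GGC", "GC"),
                        alt = c("G", "G"))
  expect_error(apply_genomic_variants(cds, overlap), "overlap")
  expect_error(apply_genomic_variants(
    cds, data.frame(position = 4, ref = "C", alt = "T")),
    "position 4")
})

test_that("translate_cds follows the standard code and stop rules", {
  expect_equal(translate_cds("ATGGCTTGA"), "MA")
  expect_equal(translate_cds("ATGTAATGA"), "M")
  expect_error(translate_cds("ATGNCT"), "ambiguous")
  expect_error(translate_cds("AT"), "codon")
  expect_warning(out <- translate_cds("ATGGCTTG"), "partial codon")
  expect_equal(out, "MA")
})

test_that("frameshifts diverge from the first affected codon", {
  ## deleting one base of codon 2 shifts the rest of the frame
  cds <- "ATGGCTTGGAAAGCTTAA"     # MAWKA
  shifted <- apply_genomic_variants(
    cds, data.frame(position = 5, ref = "CT", alt = "C"))
  prot <- suppressWarnings(translate_cds(shifted))
  expect_equal(substr(prot, 1, 1), "M")
  expect_false(prot == "MAWKA")
})

test_that("diff_proteins trims, classifies, and normalizes 3'-most", {
  expect_equal(diff_proteins("MAK", "MVK")$description, "A2V")
  expect_equal(diff_proteins("MAAK", "MAK")$description, "A3del")
  expect_equal(diff_proteins("MKR", "M")$description, "K2_R3del")
  expect_equal(diff_proteins("MAKL", "MAKQL")$description, "K3_L4insQ")
  expect_equal(diff_proteins("MAK", "MAAK")$description, "A2dup")
  expect_equal(diff_proteins("MAKLV", "MCKLW")$description, "A2_V5delinsCKLW")
  d <- diff_proteins("MAK", "MAK")
  expect_true(d$synonymous)
  expect_true(is.na(d$description))
})

test_that("ambiguous deletions take the 3'-most equivalent placement", {
  ## enumerate all single-residue deletions that give the same mutant
  set.seed(21)
  for (i in 1:200) {
    q <- random_seq(sample(4:12, 1))
    p <- sample.int(nchar(q), 1)
    mutant <- paste0(substr(q, 1, p - 1), substring(q, p + 1))
    d <- diff_proteins(q, mutant)
    if (d$synonymous) next
    equivalent <- which(vapply(seq_len(nchar(q)), function(j)
      paste0(substr(q, 1, j - 1), substring(q, j + 1)) == mutant, logical(1)))
    expect_match(d$description, "del$")
    pos <- as.integer(sub("^[A-Z]([0-9]+)del$", "\\1", d$description))
    expect_equal(pos, max(equivalent))
  }
})

test_that("diff -> parse round trip reconstructs mutants over fuzzed edits", {
  set.seed(31)
  for (i in 1:2000) {
    q <- random_seq(sample(3:40, 1))
    mutant <- random_edit(q)
    d <- diff_proteins(q, mutant)
    if (d$synonymous) {
      expect_identical(mutant, q)
      next
    }
    expect_identical(parse_variant(d$description, q)$mutant_seq, mutant)
  }
})

test_that("build_ancestor_query applies ancestral variants to the reference", {
  expect_equal(build_ancestor_query("MAKL", character()), "MAKL")
  expect_equal(build_ancestor_query("MAKL", c("A2V", "L4del")), "MVK")
})

test_that("ancestor-adjusted diffs are reported in ancestor coordinates", {
  ## reference MAWK; ancestor carries A2V; an MA line additionally W3R
  m <- demo_gene_model("+")
  anc <- data.frame(gene_id = "gX", position = 5, ref = "C", alt = "T")
  ref_cds <- splice_cds(m)
  expect_equal(translate_cds(ref_cds), "MAWK")
  expect_equal(
    translate_cds(splice_cds(m, apply_genomic_variants(m$genomic_seq, anc))),
    "MVWK")
  muts <- data.frame(line_id = "L1", gene_id = "gX", position = 13,
                     ref = "T", alt = "C", stringsAsFactors = FALSE)
  out <- mutate_study(list(m), muts, anc)
  expect_equal(out$queries[["gX.t1"]], "MVWK")
  expect_equal(out$variants$description, "W3R")
  expect_true(out$variants$ancestral_divergent)
})

test_that("a reverted ancestral frameshift lengthens the query's successor", {
  ## single-exon gene; the ancestor deleted one base of codon 3,
  ## truncating the protein; an MA line restores it
  cds <- "ATGGCTTGGAAAGCTTAA"    # reference protein MAWKA
  m <- gene_model("gF", "gF.t1", "+", 1, nchar(cds), cds)
  anc <- data.frame(gene_id = "gF", position = 7, ref = "TG", alt = "T")
  muts <- data.frame(line_id = "L1", gene_id = "gF", position = 7,
                     ref = "T", alt = "TG", stringsAsFactors = FALSE)
  out <- suppressWarnings(mutate_study(list(m), muts, anc))
  expect_lt(nchar(out$queries[["gF.t1"]]), nchar("MAWKA"))
  expect_equal(out$variants$mutant_seq, "MAWKA")
  expect_gt(nchar(out$variants$mutant_seq), nchar(out$queries[["gF.t1"]]))
})

test_that("joint application differs from scoring single mutants separately", {
  m <- demo_gene_model("+")
  muts <- data.frame(line_id = c("L1", "L1"), gene_id = "gX",
                     position = c(4, 5), ref = c("G", "C"), alt = c("T", "A"),
                     stringsAsFactors = FALSE)
  out <- mutate_study(list(m), muts, NULL)
  ## one record for the line, carrying both edits in a single protein
  expect_equal(nrow(out$variants), 1L)
  expect_equal(out$variants$mutant_seq,
               parse_variant(out$variants$description, "MAWK")$mutant_seq)
  expect_equal(out$variants$description, "A2Y")
})

test_that("non-exonic variants are skipped with a message", {
  m <- demo_gene_model("+")     # intron at 7..12
  muts <- data.frame(position = 8, ref = "T", alt = "A")
  expect_message(res <- mutate_transcript(m, muts), "non-exonic")
  expect_equal(res$protein, "MAWK")
})
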