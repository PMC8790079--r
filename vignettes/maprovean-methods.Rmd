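---
title: "Scoring mutant proteins and predicting MA-line fitness with maprovean"
author: "maprovean authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring mutant proteins and predicting MA-line fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maprovean)
```

## The problem

Mutation accumulation (MA) experiments propagate replicate lines through
repeated single-cell bottlenecks so that new mutations fix nearly
neutrally. Pairing the sequenced mutations of each line with replicated
growth assays gives a rare opportunity to ask whether computational
variant-effect predictions carry information about *realized* fitness.
`maprovean` implements the full chain needed to ask that question with a
PROVEAN-style delta alignment score: genomic mutation tables are turned
into mutant proteins, each protein variant is scored against clusters of
homologous supporting sequences, scores are collapsed into per-line
summary statistics, and competing fixed-origin regressions of relative
fitness on those statistics are ranked by small-sample corrected AIC
(AICc).

## The delta alignment score

For a query protein $q$, a variant $v(q)$, and a supporting set of
homologs partitioned into clusters $C_1, \dots, C_k$, the score is

$$ S(v) \;=\; \frac{1}{k}\sum_{i=1}^{k}\Big(
   \overline{A}(v(q), C_i) - \overline{A}(q, C_i)\Big), $$

where $\overline{A}(x, C)$ is the mean semi-global (ends-free)
affine-gap alignment score of $x$ against the members of $C$ under
BLOSUM62. A variant is classified **deleterious** when $S(v)$ falls
strictly below a threshold (default $-2.5$). Identical query and mutant
give $S = 0$ exactly; with a supporting set equal to the query, a single
substitution's score reduces to the BLOSUM62 difference (for example
W→A gives $-3 - 11 = -14$), which the test suite uses as a closed-form
anchor.

Choices the description of the score leaves open, and what this package
does:

* **Alignment flavor and gap costs.** Ends-free ("overlap") alignment
  with gap open 10 and gap extend 1 (a gap of length $L$ costs
  $10 + L$). Both are recorded in `scoring_config()` and overridable.
* **Clustering.** Supporting sequences are clustered greedily in
  decreasing length order; a sequence joins the first cluster whose
  representative (founding, longest member) shares at least 75%
  identity, defined as matches divided by alignment columns of the
  global pairwise alignment, gaps counted as columns. This mirrors the
  greedy behavior of CD-HIT-style tools.
* **Cluster selection and averaging.** The 30 clusters most similar to
  the query (by representative identity, ties to the longer
  representative, then input order) are scored; means are taken within
  clusters first and then across clusters, so cluster sizes do not
  reweight the score.
* **Unscorable variants.** An empty supporting set, an empty mutant
  (full truncation), or a failed alignment yields an `unscored` flag
  rather than a number, and unscored proteins are excluded from all
  downstream statistics (their count is reported per line).

The BLAST search that would normally assemble the supporting set is
deliberately out of scope: supporting sets are inputs (or are
simulated), which keeps results reproducible and independent of a
changing external database.

## From genomic mutations to protein variants

`mutate_study()` applies each line's variants jointly per gene (two
mutations in one gene produce one doubly-mutant protein), splices exons
(shifting boundaries downstream of indels), translates with the
standard code — premature stops truncate, trailing partial codons are
dropped with a warning — and describes the protein change against the
**ancestor query**: the reference protein with any ancestral variants
applied. Scoring against the ancestor rather than the reference removes
reference bias; `build_ancestor_query()` exposes the same adjustment at
the protein level.

Variant descriptions use the HGVS protein subset without the `p.`
prefix (`A123T`, `K45del`, `K45_L46insQ`, `K45dup`,
`A12_Y20delinsGG`). Ambiguous indel placements are normalized to the
3'-most equivalent position so repeat regions get deterministic
descriptions. Multiple edits to one protein collapse into a single
spanning deletion-insertion, which the type summary reports as
*complex*. Insertions at the very first or last residue have no
flanking pair in this notation and are encoded as single-residue
deletion-insertions; every emitted description re-applies to the query
to reproduce the mutant exactly, a property fuzz-tested over $10^4$
random edits.

Alternative transcripts of a gene are scored independently and reduced
with `gene_level_score()` to the minimum score over transcripts, the
conservative rule for "is any product of this gene damaged".

## Per-line statistics and fitness models

For each line, `summarize_line()` counts scored mutant proteins
($\Psi_{tot}$), those scoring below the threshold ($\Psi_{del}$), those
with $|S|$ above the threshold magnitude ($\Psi_{abs}$ — a $+3$ score
counts here but not in $\Psi_{del}$), the non-deleterious remainder
$\Psi_{non\_del} = \Psi_{tot} - \Psi_{del}$, the same counts restricted
to an essential-gene list, and the log-compressed aggregate
$\Sigma_{tot} = \log(1 - \sum S)$. The log transform tames the extreme
negative scores of truncated proteins; when the score sum reaches 1
(possible with large positive scores) the statistic is undefined and
flagged rather than silently dropped.

Relative fitness is the block-adjusted line mean minus the matched
control mean (`relative_fitness()`). Blocks enter as fixed effects, so
adding a constant to every measurement of one block provably leaves all
values unchanged; a random-block formulation would shrink estimates and
break that exact invariance. Controls define the baseline, which
motivates the models' **fixed origin**: an ancestor with no new
mutations has predictor 0 and relative fitness 0, so regressions run
through (0, 0). `fit_origin_lm()` (optionally multi-predictor, e.g. the
$\Psi_{del} + \Psi_{non\_del}$ decomposition, or with a relative genome
size covariate) and `fit_origin_mixed()` (per-ancestor random slopes,
maximum likelihood so likelihoods are comparable across fixed-effect
structures) return `ma_fit` objects ranked by

$$ \mathrm{AICc} = -2\ln L + 2K + \frac{2K(K+1)}{n-K-1}, $$

with $K$ counting every estimated parameter including variance
components. AICc can be negative when residual variance is small; only
differences matter. `threshold_sweep()` recomputes $\Psi_{del}$ on a
cutoff grid (default $-10$ to $0$ by $0.25$), refits the origin model,
and records the AICc alongside the pooled proportion of variants called
deleterious; cutoffs where every line's count is zero are recorded as
undefined rather than fitted.

`deleterious_contingency()`, `score_ranksum()`, `median_ci()` and
`grouped_deleterious_model()` implement the reference-bias comparisons
of pre-existing ancestral variants against new mutations: Fisher's
exact test on deleterious classification, a rank-sum test on the scores
(exact enumeration up to combined $n = 20$, tie-corrected normal
approximation beyond), a seeded percentile bootstrap for median CIs
(the CI construction is unstated in the sources this mirrors, so the
percentile bootstrap is this package's documented choice), and a
random-intercept logistic model with a flagged fixed-effect fallback
and profile-based p-values under separation.

## The synthetic study generator

`simulate_ma_study()` generates complete toy studies so every stage can
be validated without downloads. What it emulates: protein families with
site-specific conservation (supporting sequences substitute each site
with probability equal to its tolerance, so conserved-site variants
score more negatively than tolerant-site ones); gene models with 1–3
exons on either strand whose splice-and-translate provably reproduces
the designed protein; Poisson numbers of genomic mutations per line
(SNVs plus occasional short indels, so frameshifts and nonsense changes
occur and receive extreme scores, as real pipelines see); ancestral
variants placed at tolerant sites, emulating standing variation already
screened by selection; and replicated growth assays with shared block
effects, matched controls, and latent line fitness stored in a truth
record.

Default conditions (chosen once as a desk-scale caricature of an MA
panel and then left alone): 2 ancestors × 10 lines, 25 proteins of mean
length 60, 8 supporting sequences per protein, 2.5 mutations per line,
3 blocks, replicate noise SD 0.02, block SD 0.01, base growth 1.0.
These sizes keep a full simulate–mutate–score–aggregate–fit cycle
around three seconds so that replicated model-selection experiments run
in minutes on one CPU; the acceptance script uses 25 replicates per
regime and the test suite 50.

True fitness is additive over mutations — no epistasis or dominance,
matching the regression models under test — with three regimes:

* `uniform_per_mutation` (default effect $-0.04$ per scored mutant
  protein): the count $\Psi_{tot}$ is the correctly specified
  predictor, and it wins the AICc comparison against $\Sigma_{tot}$ in
  essentially all replicates.
* `score_linked` (effect $0.005 \times S$ per variant): the aggregate
  score carries the signal and $\Sigma_{tot}$ wins.
* `deleterious_linked` (effects only from variants with $S < -2$,
  proportional to magnitude): an interior deleterious cutoff is
  optimal, and the threshold sweep's argmin lands inside the grid,
  typically near $-3$.

One subtlety is worth documenting. Under strictly score-proportional
effects, nonsense and frameshift variants — whose alignment scores are
in the hundreds negative — would dominate the fitness variance, and the
best count predictor then isolates those few extreme proteins at a very
negative cutoff: the sweep's argmin slides to the grid edge. That is a
real property of the idealized proportional model, not of the sweep
machinery. The interior-optimum regime is therefore simulated with
missense changes only (`missense_only = TRUE`, `indel_prob = 0`) and a
higher mutation rate (6 per line) so several moderate causal variants
accumulate per line; truncation pseudo-scores are not proportional
effect measurements, and the scoring method itself was never validated
for nonsense variants.

What the generator does **not** emulate — and hence what passing tests
do not certify about real data: BLAST-derived supporting sets with
phylogenetic structure and database biases, epistasis and dominance,
mutation-rate heterogeneity along the genome, aneuploidy (relative
genome size is accepted as a covariate but not generated), linked
environments, or realistic protein length and composition
distributions.

## Numerical choices and degenerate inputs

* Strict inequality for the deleterious call ($S <$ threshold);
  sweeping the threshold never changes scores, only classifications.
* Greedy clustering ties: stable sort keeps input order among
  equal-length sequences; cluster selection breaks identity ties by
  longer representative, then input order. Given those rules the score
  is invariant to supporting-set order.
* Identity uses alignment columns computed arithmetically
  (`len(a) + len(b) - matches - mismatches`), identical to counting
  columns of the aligned strings but much faster. Co-optimal alignments
  can differ in match count; the package takes the aligner's traceback.
* `summarize_line()` with no scored rows returns all-zero counts and
  $\Sigma_{tot} = \log(1) = 0$ — a line with only synonymous mutations
  still has a summary.
* Through-origin fits refuse identically-zero predictors (the slope is
  unidentifiable); mixed fits flag singular random-slope variance
  instead of hiding it; model selection refuses fits on different
  $n$.
* Genes absent from the essential list are treated as non-essential.
* All simulation randomness flows from a single mandatory seed;
  identical seed and configuration give byte-identical artifacts, which
  the pipeline manifest (MD5 per file) makes checkable.

## Known limitations

Scores from desk-scale supporting sets are *not* expected to match
scores computed against a live protein database — the supporting set
is the dominant unknown. The AIC printed by this package is the
standard $-2\ln L + 2K$ (and AICc accordingly); definitions that
differ by a factor or sign convention appear in the literature, so
comparisons should use differences computed within one framework. The
through-origin design gains power from controls but inflates apparent
fits when controls are absent; the free-intercept refit
(`fixed_origin = FALSE`) is the appropriate sensitivity analysis and is
a genuinely different model, not a reparameterization.
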