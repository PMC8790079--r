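Package: maprovean
Title: Alignment-Based Variant Effect Scores as Fitness Predictors in
    Mutation Accumulation Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates alignment-based variant-effect scores as predictors of
    aggregate fitness in mutation accumulation (MA) experiments. Provides
    in-silico CDS mutagenesis and translation, a desk-scale PROVEAN-style
    delta-alignment scorer with greedy clustering of supporting sequences,
    per-line summary statistics, fixed-origin fitness regressions ranked by
    small-sample corrected AIC, a deleterious-threshold sweep, reference-bias
    diagnostics, and a synthetic MA-study generator for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    lme4,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
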