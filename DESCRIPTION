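Package: sigprog
Title: Perturbation-Derived Gene Signatures and Composite Prognostic Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for deriving prognostic gene signatures from paired
    perturbation experiments (knockdown and over-expression) and evaluating them
    in a patient cohort. Provides per-gene Welch differential statistics with
    across-gene standardized effects, Stouffer gene-set Z-score enrichment and
    cross-experiment comparison, weighted Kolmogorov-Smirnov enrichment scores
    with a permutation null, intersection-based signature derivation,
    geometric-mean-difference signature scoring, a four-factor composite
    prognostic score (stage, marker, and two signature scores), survival
    statistics (Kaplan-Meier, log-rank, univariable Cox, Harrell's concordance),
    and a synthetic-data generator that emulates the paired experiments and a
    cohort whose hazard increases with the composite score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
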