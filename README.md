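# sigprog

Perturbation-derived gene signatures and composite prognostic scoring for
survival cohorts.

## The problem

A regulator (here, an nc886-like noncoding RNA measured by qRT-PCR) is
silenced in a fraction of tumors, and its loss is suspected to drive risk.
Two complementary perturbation experiments — a knockdown (KD) in
marker-expressing cells and an ectopic over-expression (EXP) — should move
the regulator's downstream programs in opposite directions. sigprog
implements the full chain that turns such a pair of experiments, plus a
patient cohort with expression arrays and survival follow-up, into:

- per-gene differential statistics (Welch t, across-gene standardized
  effect *z*);
- signed gene-set Z-scores, `Z_S = Σ z_g / √m` (Stouffer), compared
  between KD and EXP by Pearson correlation, and reciprocal top-N overlap
  tested with the one-sided hypergeometric tail (Fisher's exact test);
- GSEA: the weighted Kolmogorov–Smirnov enrichment score of an a-priori
  set against genes ranked by correlation with the cohort marker, with a
  permutation null;
- up/down gene signatures, derived either by intersecting a pathway set
  with doubly significant genes and validating against the cohort marker,
  or by filtering a curated list at |z| > 2, p < 0.05;
- per-sample signature scores: the difference of geometric means between
  the up and down lists (an arithmetic difference of means in log2 space);
- a composite prognostic score 0–4 summing four adverse binaries (advanced
  TNM stage, below-median marker, above-median AKT-signature score,
  above-median cell-cycle score), evaluated with Kaplan–Meier curves, the
  log-rank test, univariable Cox regression, and Harrell's concordance
  index.

A synthetic-data module (`simulation_config()`,
`simulate_perturbation_pair()`, `simulate_patient_cohort()`) generates
inputs with exactly the structure this chain assumes — opposite-direction
planted set effects, a bimodal marker, signature genes correlated with the
marker, and survival times whose hazard scales as
`λ0 · exp(β · score)` — so every stage is testable against a known truth.

It is aimed at computational biologists reanalyzing perturbation + cohort
designs, and at anyone needing a compact, oracle-tested reference for
these survival and enrichment statistics.

## Worked example

The one-command demo runs the whole chain on synthetic study conditions
(10,000 genes, triplicate arms, 108 patients):

```r
library(sigprog)
s <- run_full(pipeline_config(seed = 7), "demo_run")

s$set_z_comparison$r      # -0.951  KD and EXP set-Z vectors anticorrelate
s$top_n_overlap$overlap   # 174 of top 1000 (p = 1.8e-14): reciprocal overlap
s$cox_composite$hr        # 1.91    hazard ratio per composite-score point
s$c_index$composite       # 0.738   highest C-index of all factors
unlist(s$km_median)       # 27.4 17.2 14.1 4.4 1.3  months, scores 0..4
```

Read: the two perturbations move gene sets in opposite directions
(r = −0.95); each extra adverse factor roughly doubles the hazard (the
generator's truth is HR 2); the composite score is more concordant with
survival than any single factor; and median survival falls monotonically
across the five strata. All tables, a `summary.json`, and a log are
written under `demo_run/`. A thin CLI wrapper lives at
`inst/scripts/run_pipeline.R`.

Real data enter through `read_expression_matrix()` (log2 TSV),
`parse_gmt()` (MSigDB GMT), `read_clinical_table()` (CSV with
`sample_id,time,event,stage_group,marker`), and `read_gene_list()`;
set `pipeline_config(simulate = FALSE, ...)` with the input paths.

## Documentation

The methods vignette
(`vignettes/perturbation-signature-prognosis.Rmd`) documents the model,
every tunable threshold, the numerical conventions (tie-breaking,
degenerate inputs, Welch small-sample calibration, the direction-selected
permutation p), what the generator does and does not emulate, and power
limits at the default study conditions.
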