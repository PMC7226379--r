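small_cfg <- function(...) {
  args <- list(n_genes = 400, n_patients = 60,
               planted_sets = c(SET = 30),
               signature_sizes = list(akt = c(up = 10, down = 6),
                                      cc = c(up = 6, down = 4)))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(censoring = 1), "censoring")
  expect_error(simulation_config(n_genes = 20,
                                 planted_sets = c(S = 50)), "planted")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_cfg(seed = 71)
  p1 <- simulate_perturbation_pair(cfg)
  p2 <- simulate_perturbation_pair(cfg)
  expect_identical(p1$kd$expr, p2$kd$expr)
  expect_identical(p1$exp$expr, p2$exp$expr)
  c1 <- simulate_patient_cohort(cfg)
  c2 <- simulate_patient_cohort(cfg)
  expect_identical(c1$expr, c2$expr)
  expect_identical(c1$cohort, c2$cohort)
  # a different seed changes the data
  p3 <- simulate_perturbation_pair(small_cfg(seed = 72))
  expect_false(identical(p1$kd$expr, p3$kd$expr))
})

test_that("the pair and the cohort plant the same signature genes", {
  cfg <- small_cfg(seed = 73)
  pair <- simulate_perturbation_pair(cfg)
  sim <- simulate_patient_cohort(cfg)
  expect_identical(pair$truth$signatures$akt$up, sim$signatures$akt$up_genes)
  expect_identical(pair$truth$signatures$cc$down,
                   sim$signatures$cc$down_genes)
})

test_that("a null pair (delta = 0) gives uniform pooled-t p-values", {
  cfg <- simulation_config(n_genes = 10000, delta = 0, seed = 74,
                           planted_sets = c(S = 50),
                           signature_sizes = list())
  pair <- simulate_perturbation_pair(cfg)
  d <- differential_table(pair$kd$expr, pair$kd$treated, pair$kd$control,
                          t_method = "pooled")
  ks <- suppressWarnings(ks.test(d$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  binom_band <- 3 * sqrt(0.05 * 0.95 / nrow(d))
  expect_lt(abs(mean(d$p < 0.05) - 0.05), binom_band)
})

test_that("a planted 5-sigma set reaches |Z| > 3 with opposite signs", {
  cfg <- simulation_config(n_genes = 3000, delta = 5, seed = 75,
                           planted_sets = c(PLANTED = 50),
                           signature_sizes = list())
  pair <- simulate_perturbation_pair(cfg)
  d_kd <- differential_table(pair$kd$expr, pair$kd$treated, pair$kd$control)
  d_ex <- differential_table(pair$exp$expr, pair$exp$treated,
                             pair$exp$control)
  z_kd <- set_z_scores(d_kd, pair$sets)$z_set
  z_ex <- set_z_scores(d_ex, pair$sets)$z_set
  expect_gt(z_kd, 3)
  expect_lt(z_ex, -3)
})

test_that("cohort contract: size, validity, truth-record consistency", {
  cfg <- small_cfg(n_patients = 108, seed = 76)
  sim <- simulate_patient_cohort(cfg)
  expect_equal(nrow(sim$cohort), 108L)
  expect_silent(as_cohort_table(sim$cohort))
  expect_equal(ncol(sim$expr), 108L)
  # composite score in the table equals the truth record
  expect_equal(sim$cohort$score_true, sim$truth$score_true)
  expect_true(all(sim$cohort$score_true %in% 0:4))
  # planted correlations have the promised orientation
  shared <- sim$cohort$sample_id
  up1 <- sim$signatures$akt$up_genes[1]
  dn1 <- sim$signatures$akt$down_genes[1]
  expect_lt(cor(sim$expr[up1, shared], sim$cohort$marker), 0)
  expect_gt(cor(sim$expr[dn1, shared], sim$cohort$marker), 0)
})

test_that("censoring calibration hits the requested fraction", {
  frac <- vapply(1:20, function(s) {
    sim <- simulate_patient_cohort(small_cfg(n_patients = 200, seed = 700 + s))
    1 - mean(sim$cohort$event)
  }, 0)
  expect_lt(abs(mean(frac) - 0.3), 0.04)
  sim0 <- simulate_patient_cohort(small_cfg(censoring = 0, seed = 77))
  expect_true(all(sim0$cohort$event == 1))
})

test_that("null cohorts (beta = 0) give uniform log-rank p across strata", {
  p_vals <- vapply(1:60, function(s) {
    sim <- simulate_patient_cohort(small_cfg(beta_score = 0,
                                             n_patients = 120,
                                             seed = 7000 + s))
    co <- sim$cohort
    if (length(unique(co$score_true)) < 2) return(NA_real_)
    log_rank_test(co$time, co$event, co$score_true)$p
  }, 0)
  p_vals <- p_vals[!is.na(p_vals)]
  ks <- suppressWarnings(ks.test(p_vals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("truth records score planted-signature recovery", {
  # Two-stage derivation at delta = 3*sigma, triplicate arms, 200 patients.
  # Stage 1 (p < 0.05 in BOTH experiments) has joint power ~0.45 at this
  # effect size, which bounds marginal recovery; conditional on passing
  # stage 1, the cohort-correlation stage (rho = 0.6, n = 200) must keep
  # and correctly orient nearly every gene.
  n_seeds <- 50
  res <- vapply(seq_len(n_seeds), function(s) {
    cfg <- simulation_config(n_genes = 600, n_patients = 200,
                             planted_sets = c(SET = 20),
                             signature_sizes = list(
                               cc = c(up = 9, down = 5),
                               akt = c(up = 10, down = 6)),
                             seed = 8000 + s)
    pair <- simulate_perturbation_pair(cfg)
    sim <- simulate_patient_cohort(cfg)
    d_kd <- differential_table(pair$kd$expr, pair$kd$treated,
                               pair$kd$control)
    d_ex <- differential_table(pair$exp$expr, pair$exp$treated,
                               pair$exp$control)
    truth <- sim$signatures$cc
    planted <- c(truth$up_genes, truth$down_genes)
    pathway <- c(planted, sample(setdiff(rownames(pair$kd$expr), planted),
                                 26))
    sig <- tryCatch(
      suppressWarnings(
        derive_pathway_signature(pathway, d_kd, d_ex, sim$expr,
                                 sim$cohort, name = "cc_hat")),
      error = function(e) NULL)
    if (is.null(sig)) return(c(NA_real_, NA_real_))
    got <- c(sig$up_genes, sig$down_genes)
    stage1 <- intersect(planted, sig$provenance$candidate_correlations$gene_id)
    oriented_ok <- all(sig$up_genes %in% c(truth$up_genes,
                                           setdiff(pathway, planted))) &&
      all(intersect(sig$up_genes, planted) %in% truth$up_genes) &&
      all(intersect(sig$down_genes, planted) %in% truth$down_genes)
    c(marginal = length(intersect(got, planted)) / length(planted),
      conditional = if (length(stage1) == 0) NA_real_
                    else length(intersect(got, stage1)) / length(stage1) *
                      oriented_ok)
  }, c(0, 0))
  marginal <- mean(res[1, ], na.rm = TRUE)
  conditional <- mean(res[2, ], na.rm = TRUE)
  # stage-2 recovery (the part the truth record can certify at this
  # effect size) is near-complete
  expect_gte(conditional, 0.8)
  # marginal recovery is governed by the double-significance power
  expect_gt(marginal, 0.35)
  expect_lt(marginal, 0.55)
})
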