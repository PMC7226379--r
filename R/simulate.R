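#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic-data generators:
#' two paired perturbation experiments (knockdown-like and
#' over-expression-like) with opposite-direction planted gene-set effects,
#' and a surgical cohort whose hazard increases with the composite
#' prognostic score.
#'
#' Defaults mirror the emulated study: triplicate arrays per arm, a
#' 108-patient cohort, a bimodal marker (silenced vs. expressing patients,
#' mixture components two component-SDs apart, mixing fraction 0.5), an
#' AKT-like signature of 34 up / 19 down genes and a cell-cycle-like
#' signature of 9 up / 5 down genes planted at correlation strength
#' `rho = 0.6` with the marker, and a per-score hazard ratio of 2
#' (`beta_score = log 2`) on an exponential baseline with 30% censoring.
#'
#' @param n_genes Number of genes (default 10000).
#' @param n_replicates Replicates per arm of each perturbation (default 3).
#' @param n_patients Cohort size (default 108).
#' @param baseline_mean,baseline_sd Mean and SD of per-gene baseline log2
#'   levels (defaults 8 and 1.5).
#' @param noise_sd Residual SD of a single measurement around its gene
#'   baseline, in log2 units (default 1); planted effect sizes are naturally
#'   read in units of this sigma.
#' @param planted_sets Named integer vector: sizes of the planted gene sets
#'   for the perturbation pair (default one 50-gene set `SET_PLANTED`).
#' @param delta Planted shift in log2 units, applied `+delta` in the
#'   knockdown-like and `-delta` in the over-expression-like experiment
#'   (default 3).
#' @param marker_means,marker_sd,marker_mix Two-component marker mixture:
#'   component means (default -1 and 1), common SD (default 1, so the means
#'   sit two SDs apart), and the fraction in the low component (default
#'   0.5).
#' @param rho Correlation strength between planted signature genes and the
#'   marker (default 0.6).
#' @param signature_sizes Named list of `c(up = ..., down = ...)` integer
#'   pairs; `up` genes are planted negatively correlated with the marker
#'   (risk orientation), `down` genes positively.
#' @param lambda0 Baseline hazard per month (default 0.02).
#' @param beta_score Log hazard ratio per composite-score point (default
#'   `log(2)`).
#' @param weibull_shape Shape of the baseline hazard; 1 (default) is the
#'   exponential case.
#' @param censoring Target censoring fraction in `[0, 1)` (default 0.3).
#' @param seed Integer RNG seed (default 1).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 10000, n_replicates = 3,
                              n_patients = 108,
                              baseline_mean = 8, baseline_sd = 1.5,
                              noise_sd = 1,
                              planted_sets = c(SET_PLANTED = 50L),
                              delta = 3,
                              marker_means = c(-1, 1), marker_sd = 1,
                              marker_mix = 0.5,
                              rho = 0.6,
                              signature_sizes = list(
                                akt = c(up = 34L, down = 19L),
                                cc = c(up = 9L, down = 5L)),
                              lambda0 = 0.02, beta_score = log(2),
                              weibull_shape = 1,
                              censoring = 0.3, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_replicates = as.integer(n_replicates),
              n_patients = as.integer(n_patients),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              noise_sd = noise_sd,
              planted_sets = planted_sets, delta = delta,
              marker_means = marker_means, marker_sd = marker_sd,
              marker_mix = marker_mix, rho = rho,
              signature_sizes = signature_sizes,
              lambda0 = lambda0, beta_score = beta_score,
              weibull_shape = weibull_shape,
              censoring = censoring, seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1L, cfg$n_replicates >= 2L, cfg$n_patients >= 4L,
            cfg$baseline_sd > 0, cfg$noise_sd > 0, cfg$marker_sd > 0,
            is.finite(cfg$delta), cfg$lambda0 > 0, cfg$weibull_shape > 0,
            cfg$marker_mix >= 0, cfg$marker_mix <= 1,
            abs(cfg$rho) < 1)
  if (cfg$censoring < 0 || cfg$censoring >= 1) {
    stop("censoring fraction must be in [0, 1)")
  }
  if (sum(cfg$planted_sets) > cfg$n_genes) {
    stop("planted sets larger than the gene universe")
  }
  n_sig <- sum(vapply(cfg$signature_sizes, sum, 0))
  if (n_sig > cfg$n_genes) stop("signature genes exceed the gene universe")
  invisible(cfg)
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

# Deterministic planted-gene assignment shared by both generators, so the
# signature genes are the same genes in the perturbation pair and in the
# cohort (they are perturbation-responsive AND marker-correlated, which is
# what the two-stage derivation assumes). Derived from cfg$seed alone.
plant_assignments <- function(cfg) {
  set.seed(cfg$seed)
  g <- gene_ids(cfg$n_genes)
  sig_sizes <- vapply(cfg$signature_sizes, sum, 0)
  pool <- sample(g, sum(cfg$planted_sets) + sum(sig_sizes))
  offset <- 0L
  sets <- list()
  for (nm in names(cfg$planted_sets)) {
    k <- cfg$planted_sets[[nm]]
    sets[[nm]] <- pool[offset + seq_len(k)]
    offset <- offset + k
  }
  signatures <- list()
  for (nm in names(cfg$signature_sizes)) {
    sz <- cfg$signature_sizes[[nm]]
    signatures[[nm]] <- list(
      up = pool[offset + seq_len(sz[["up"]])],
      down = pool[offset + sz[["up"]] + seq_len(sz[["down"]])])
    offset <- offset + sum(sz)
  }
  list(genes = g, sets = sets, signatures = signatures)
}

#' Simulate a paired knockdown / over-expression experiment
#'
#' Generates two expression matrices with shared per-gene baselines
#' (`Normal(baseline_mean, baseline_sd)`), Gaussian measurement noise of SD
#' `noise_sd`, and planted gene sets shifted by `+delta` in the treated arm
#' of the knockdown-like experiment and by `-delta` in the
#' over-expression-like experiment. The opposite signs are what make the
#' two experiments' set-level Z vectors anticorrelate.
#'
#' @param cfg A [simulation_config()].
#' @return A list with elements `kd` and `exp` (each a list of `expr`
#'   matrix, `treated` and `control` sample ids), `sets` (the planted sets
#'   as a named list usable as a gene-set collection), and `truth`
#'   (planted genes and per-experiment directions).
#' @export
simulate_perturbation_pair <- function(cfg) {
  validate_simulation_config(cfg)
  plan <- plant_assignments(cfg)
  set.seed(cfg$seed + 1L)
  g <- plan$genes
  baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  set_genes <- unlist(plan$sets, use.names = FALSE)
  sig_up <- unlist(lapply(plan$signatures, `[[`, "up"), use.names = FALSE)
  sig_down <- unlist(lapply(plan$signatures, `[[`, "down"),
                     use.names = FALSE)

  one_experiment <- function(direction, prefix) {
    nr <- cfg$n_replicates
    cols <- c(paste0(prefix, "_trt_", seq_len(nr)),
              paste0(prefix, "_ctl_", seq_len(nr)))
    m <- baseline +
      matrix(stats::rnorm(cfg$n_genes * 2 * nr, 0, cfg$noise_sd),
             nrow = cfg$n_genes)
    dimnames(m) <- list(g, cols)
    trt <- seq_len(nr)
    # planted sets and up-oriented signature genes move with `direction`;
    # down-oriented signature genes move against it
    shift_up <- c(set_genes, sig_up)
    m[shift_up, trt] <- m[shift_up, trt] + direction * cfg$delta
    if (length(sig_down)) {
      m[sig_down, trt] <- m[sig_down, trt] - direction * cfg$delta
    }
    list(expr = m, treated = cols[trt], control = cols[nr + trt])
  }
  kd <- one_experiment(+1, "KD")
  ex <- one_experiment(-1, "EXP")
  list(kd = kd, exp = ex, sets = plan$sets,
       truth = list(planted_genes = c(set_genes, sig_up, sig_down),
                    sets = plan$sets, signatures = plan$signatures,
                    direction_kd = +1, direction_exp = -1,
                    delta = cfg$delta))
}

#' Simulate a patient cohort with score-dependent hazard
#'
#' Draws a bimodal continuous marker (two-component Gaussian mixture), a
#' cohort expression matrix in which planted signature genes correlate with
#' the marker at strength `rho` (up-oriented genes negatively, down-oriented
#' genes positively, matching the marker-low-is-high-risk orientation), a
#' Bernoulli(0.5) stage group, and survival times from a proportional-hazards
#' Weibull (exponential by default) model with hazard
#' `lambda0 * exp(beta_score * score) * shape * t^(shape-1)`, where `score`
#' is the four-factor composite computed from the generated data itself.
#' Censoring times are independent Uniform(0, u) with `u` calibrated by
#' root-finding so the expected censored fraction matches `cfg$censoring`.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `expr` (genes x patients log2 matrix), `cohort`
#'   (validated cohort table with appended columns `akt_score`, `cc_score`,
#'   `score_true`), `signatures` (list of planted `signature_definition`
#'   objects), and `truth` (planted genes, true composite scores, hazard
#'   parameters, censoring bound).
#' @export
simulate_patient_cohort <- function(cfg) {
  validate_simulation_config(cfg)
  plan <- plant_assignments(cfg)
  set.seed(cfg$seed + 2L)
  n <- cfg$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  g <- plan$genes

  comp_low <- stats::runif(n) < cfg$marker_mix
  marker <- stats::rnorm(n,
                         ifelse(comp_low, cfg$marker_means[1L],
                                cfg$marker_means[2L]),
                         cfg$marker_sd)
  marker_std <- as.numeric(scale(marker))

  baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  expr <- baseline +
    matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$noise_sd),
           nrow = cfg$n_genes)
  dimnames(expr) <- list(g, ids)

  signatures <- list()
  plant <- function(genes, sign_r) {
    # replace noise with a marker-correlated signal of the same marginal SD
    k <- length(genes)
    noise <- matrix(stats::rnorm(k * n, 0, cfg$noise_sd), nrow = k)
    signal <- sign_r * cfg$rho * rep(marker_std, each = k) +
      sqrt(1 - cfg$rho^2) * noise / cfg$noise_sd
    expr[genes, ] <<- baseline[match(genes, g)] + signal * cfg$noise_sd
  }
  for (nm in names(cfg$signature_sizes)) {
    up <- plan$signatures[[nm]]$up
    down <- plan$signatures[[nm]]$down
    plant(up, -1)   # risk genes rise as the marker falls
    plant(down, +1)
    signatures[[nm]] <- signature_definition(
      name = nm, up_genes = up, down_genes = down,
      provenance = list(method = "planted", rho = cfg$rho))
  }

  stage_group <- stats::rbinom(n, 1L, 0.5)
  marker_low <- 1L - dichotomize_by_median(marker)$high
  sig_high <- lapply(signatures, function(s) {
    dichotomize_by_median(signature_score(expr, s)$score)$high
  })
  cs <- composite_score(stage_group, marker_low,
                        sig_high[[1L]], sig_high[[2L]])
  score <- cs$score

  rate <- cfg$lambda0 * exp(cfg$beta_score * score)
  shape <- cfg$weibull_shape
  # S(t) = exp(-rate * t^shape); inverse-CDF sampling
  t_event <- (-log(stats::runif(n)) / rate)^(1 / shape)

  if (cfg$censoring > 0) {
    u_max <- calibrate_uniform_censoring(rate, shape, cfg$censoring)
    t_cens <- stats::runif(n, 0, u_max)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  } else {
    u_max <- Inf
    event <- rep(1L, n)
    time <- t_event
  }

  cohort <- as_cohort_table(data.frame(
    sample_id = ids, time = time, event = event,
    stage_group = stage_group, marker = marker,
    akt_score = signature_score(expr, signatures[[1L]])$score,
    cc_score = signature_score(expr, signatures[[2L]])$score,
    score_true = score, stringsAsFactors = FALSE))

  list(expr = expr, cohort = cohort, signatures = signatures,
       truth = list(score_true = score, beta_score = cfg$beta_score,
                    lambda0 = cfg$lambda0, censor_upper = u_max,
                    up_genes = lapply(signatures, `[[`, "up_genes"),
                    down_genes = lapply(signatures, `[[`, "down_genes")))
}

# Expected censored fraction under C ~ Uniform(0, u) and
# S_i(t) = exp(-rate_i t^shape):  mean_i (1/u) int_0^u S_i(t) dt,
# monotone decreasing in u; solved by uniroot.
calibrate_uniform_censoring <- function(rate, shape, target) {
  expected <- function(u) {
    mean(vapply(unique(rate), function(r) {
      if (shape == 1) {
        (1 - exp(-r * u)) / (r * u)
      } else {
        stats::integrate(function(t) exp(-r * t^shape), 0, u,
                         rel.tol = 1e-8)$value / u
      }
    }, 0)[match(rate, unique(rate))])
  }
  lo <- 1e-6; hi <- 1
  while (expected(hi) > target && hi < 1e9) hi <- hi * 2
  if (expected(hi) > target) stop("unreachable censoring fraction")
  stats::uniroot(function(u) expected(u) - target, c(lo, hi),
                 tol = 1e-6)$root
}
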