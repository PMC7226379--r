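#' Dichotomize a continuous variable at its median
#'
#' Values at or above the median are coded "high" (1); values below are
#' "low" (0). The `>=` rule makes even-sized and tied cohorts
#' deterministic. The caller maps high/low onto the risk coding (for the
#' marker, low expression is the adverse state, so `marker_low = 1 - high`).
#'
#' @param values Numeric vector (>= 2 values, not all identical).
#' @return A list with `high` (integer 0/1 vector, names preserved) and
#'   `median`.
#' @export
dichotomize_by_median <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (!all(is.finite(values))) stop("values must be finite")
  med <- stats::median(values)
  if (all(values == values[1L])) stop("degenerate dichotomy: all values ",
                                      "identical")
  list(high = stats::setNames(as.integer(values >= med), names(values)),
       median = med)
}

#' Four-factor composite prognostic score
#'
#' Sums four adverse binary factors per patient: advanced TNM stage
#' (III-IV), below-median marker, above-median AKT signature score, and
#' above-median cell-cycle signature score. The result is an integer 0-4;
#' score 4 marks the highest-risk stratum.
#'
#' @param stage_group 0 (TNM I-II) or 1 (TNM III-IV).
#' @param marker_low 1 if the marker is below the cohort median.
#' @param akt_high 1 if the AKT signature score is at or above the median.
#' @param cc_high 1 if the cell-cycle signature score is at or above the
#'   median.
#' @return A list with `score` (integer vector 0-4) and `label` (factor
#'   with levels `"score 0"` ... `"score 4"`).
#' @export
composite_score <- function(stage_group, marker_low, akt_high, cc_high) {
  factors <- list(stage_group = stage_group, marker_low = marker_low,
                  akt_high = akt_high, cc_high = cc_high)
  n <- unique(lengths(factors))
  if (length(n) != 1L) stop("factor vectors must have equal length")
  for (nm in names(factors)) {
    f <- factors[[nm]]
    if (anyNA(f) || !all(f %in% c(0, 1))) {
      stop("missing or non-binary factor: ", nm)
    }
  }
  score <- as.integer(stage_group + marker_low + akt_high + cc_high)
  list(score = score,
       label = factor(paste("score", score),
                      levels = paste("score", 0:4)))
}

#' Kaplan-Meier product-limit estimate
#'
#' Events and censorings tied at the same time are resolved events-first
#' (censored subjects remain in the risk set for deaths at their own time),
#' the standard product-limit convention.
#'
#' @param times Positive survival times.
#' @param events 0/1 event indicators.
#' @return A list of class `km_curve` with `time` (distinct observed times,
#'   ascending), `n_risk`, `n_event`, `n_censor`, and `surv` (non-increasing,
#'   starting from 1 at time 0).
#' @export
km_estimate <- function(times, events) {
  check_surv_input(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv),
            class = "km_curve")
}

#' Median survival time from a Kaplan-Meier curve
#'
#' Smallest observed time at which the survival estimate drops to 0.5 or
#' below; `Inf` when the curve never reaches 0.5.
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @return A single number (possibly `Inf`).
#' @export
km_median <- function(curve) {
  below <- which(curve$surv <= 0.5)
  if (length(below) == 0L) return(Inf)
  curve$time[below[1L]]
}

#' Log-rank test across two or more groups
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' at each distinct event time; chi-square with k-1 degrees of freedom.
#'
#' @param times Positive survival times.
#' @param events 0/1 event indicators (at least one event overall).
#' @param groups Group labels (2 or more non-empty groups).
#' @return A list with `chi_square`, `df`, `p`.
#' @export
log_rank_test <- function(times, events, groups) {
  check_surv_input(times, events)
  groups <- as.factor(groups)
  if (any(table(groups) == 0L)) stop("a group level has no subjects")
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (sum(events) == 0L) stop("no events observed")
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1L
  list(chi_square = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Univariable Cox proportional-hazards regression
#'
#' Maximizes the partial likelihood by Newton-Raphson (convergence
#' tolerance 1e-8, at most 50 iterations) with Breslow handling of tied
#' event times by default; Efron is available behind the `ties` flag.
#' Non-convergence or monotone likelihood (complete separation, detected
#' as an extreme coefficient with an exploding standard error) is flagged
#' in the result rather than failing silently.
#'
#' @param times Positive survival times.
#' @param events 0/1 event indicators (at least one event).
#' @param covariate Numeric covariate, non-constant.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A list with `beta` (log hazard ratio), `hr`, `se`, `wald_p`,
#'   `converged`.
#' @export
cox_univariable <- function(times, events, covariate,
                            ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  check_surv_input(times, events)
  covariate <- as.numeric(covariate)
  if (sum(events) == 0L) stop("no events observed")
  if (stats::sd(covariate) == 0) stop("covariate is constant")
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ covariate,
                    ties = ties,
                    control = survival::coxph.control(eps = 1e-8,
                                                      iter.max = 50)),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(fit$var)))
  if (!is.finite(beta) || !is.finite(se) ||
      (abs(beta) > 10 && se > 10)) {
    converged <- FALSE
  }
  list(beta = beta, hr = exp(beta), se = se,
       wald_p = 2 * stats::pnorm(-abs(beta / se)),
       converged = converged)
}

#' Harrell's concordance index
#'
#' The probability, over comparable patient pairs, that the patient with
#' the higher risk score fails first. A pair is comparable when the
#' ordering of the event times is determinable: the shorter time ends in an
#' event, or the times are tied with exactly one event (the death precedes
#' the censoring). Pairs tied on time with the same event status are not
#' comparable. Risk-score ties contribute 0.5.
#'
#' @param times Positive survival times.
#' @param events 0/1 event indicators.
#' @param risk Per-patient risk scores (higher = worse expected outcome).
#' @return A list with `c_index`, `comparable`, `concordant`, `discordant`,
#'   `tied`.
#' @export
harrell_c <- function(times, events, risk) {
  check_surv_input(times, events)
  stopifnot(length(risk) == length(times))
  fit <- survival::concordance(survival::Surv(times, events) ~ risk,
                               reverse = TRUE)
  cnt <- as.numeric(fit$count)
  names(cnt) <- names(fit$count)
  concordant <- cnt[["concordant"]]
  discordant <- cnt[["discordant"]]
  tied <- cnt[["tied.x"]]
  comparable <- concordant + discordant + tied
  if (comparable == 0) stop("no comparable pairs")
  list(c_index = (concordant + 0.5 * tied) / comparable,
       comparable = comparable, concordant = concordant,
       discordant = discordant, tied = tied)
}

check_surv_input <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input")
  if (length(times) != length(events)) stop("times and events differ in ",
                                            "length")
  if (!all(is.finite(times)) || any(times <= 0)) stop("times must be ",
                                                      "positive and finite")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  invisible(TRUE)
}
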