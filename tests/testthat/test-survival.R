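test_that("median dichotomization uses the >= rule", {
  d <- dichotomize_by_median(c(1, 2, 3, 4))
  expect_equal(d$median, 2.5)
  expect_equal(unname(d$high), c(0L, 0L, 1L, 1L))
  d3 <- dichotomize_by_median(c(1, 2, 3))
  expect_equal(unname(d3$high), c(0L, 1L, 1L))  # the median itself is high
  expect_error(dichotomize_by_median(c(5, 5, 5)), "degenerate")
  expect_error(dichotomize_by_median(3), "at least 2")
})

test_that("composite score sums the four adverse factors", {
  cs <- composite_score(stage_group = c(1, 0, 1, 0),
                        marker_low = c(1, 0, 1, 0),
                        akt_high = c(1, 0, 0, 1),
                        cc_high = c(1, 0, 0, 1))
  expect_equal(cs$score, c(4L, 0L, 2L, 2L))
  expect_equal(as.character(cs$label),
               c("score 4", "score 0", "score 2", "score 2"))
  expect_equal(levels(cs$label), paste("score", 0:4))
  expect_error(composite_score(1, 1, 1, NA), "akt|cc|missing")
  expect_error(composite_score(2, 0, 0, 0), "stage_group")
})

test_that("all 16 factor combinations give exactly five strata, max 4", {
  grid <- expand.grid(s = 0:1, m = 0:1, a = 0:1, c = 0:1)
  cs <- composite_score(grid$s, grid$m, grid$a, grid$c)
  expect_setequal(unique(cs$score), 0:4)
  expect_equal(max(cs$score), 4L)
  expect_equal(cs$score, grid$s + grid$m + grid$a + grid$c,
               ignore_attr = TRUE)
})

test_that("KM estimator matches the hand product-limit", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 1 / 3))
  expect_equal(km$n_risk, c(3, 2, 1))
  # all censored -> survival stays 1
  km2 <- km_estimate(c(1, 2), c(0, 0))
  expect_true(all(km2$surv == 1))
  # single subject with an event
  km3 <- km_estimate(5, 1)
  expect_equal(km3$surv, 0)
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("KM matches brute-force product over event times for n <= 8", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    times <- sample(1:5, n, replace = TRUE)  # force ties
    events <- rbinom(n, 1, 0.6)
    if (sum(events) == 0) events[1] <- 1
    km <- km_estimate(times, events)
    # oracle: walk distinct times; events leave first, then censorings
    surv <- 1
    for (i in seq_along(km$time)) {
      t <- km$time[i]
      at_risk <- sum(times >= t)
      d <- sum(times == t & events == 1)
      expect_equal(km$n_risk[i], at_risk)
      expect_equal(km$n_event[i], d)
      surv <- surv * (1 - d / at_risk)
      expect_equal(km$surv[i], surv, tolerance = 1e-12)
    }
  }
})

test_that("KM median is the first time the curve reaches 0.5", {
  expect_equal(km_median(km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))), 2)
  expect_equal(km_median(km_estimate(c(1, 2), c(0, 0))), Inf)
})

test_that("log-rank handles the toy and identical-group cases", {
  lr <- log_rank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$chi_square, 2.882353, tolerance = 1e-6)
  expect_equal(lr$df, 1L)
  # identical groups: duplicate every subject into both arms
  t0 <- c(2, 4, 6); e0 <- c(1, 0, 1)
  lr0 <- log_rank_test(c(t0, t0), c(e0, e0), rep(c("A", "B"), each = 3))
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)
  expect_error(log_rank_test(t0, e0, c("A", "A", "A")), "2 groups")
  expect_error(log_rank_test(t0, c(0, 0, 0), c("A", "A", "B")), "no events")
})

test_that("log-rank chi-square matches the hand O-E evaluation", {
  set.seed(62)
  times <- c(1, 3, 3, 5, 7, 8, 9, 12)
  events <- c(1, 1, 0, 1, 1, 0, 1, 1)
  groups <- c(1, 2, 1, 2, 1, 2, 1, 2)
  lr <- log_rank_test(times, events, groups)
  # independent hand evaluation: O - E and hypergeometric variance per
  # distinct event time, for group 1
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    n_t <- sum(times >= t)
    n1_t <- sum(times >= t & groups == 1)
    d_t <- sum(times == t & events == 1)
    d1_t <- sum(times == t & events == 1 & groups == 1)
    o_minus_e <- o_minus_e + d1_t - d_t * n1_t / n_t
    if (n_t > 1) {
      v <- v + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  expect_equal(lr$chi_square, o_minus_e^2 / v, tolerance = 1e-9)
})

test_that("log-rank is invariant to group relabeling and matches a
           permutation null on a 5-group case", {
  set.seed(63)
  # the chi-square reference is asymptotic, so the permutation comparison
  # is run at a sample size where that approximation is in its regime
  n <- 120
  times <- rexp(n, 0.1) + 0.1
  events <- rbinom(n, 1, 0.7)
  groups <- sample(1:5, n, replace = TRUE)
  lr <- log_rank_test(times, events, groups)
  relab <- c(3, 5, 1, 2, 4)[groups]
  expect_equal(log_rank_test(times, events, relab)$chi_square,
               lr$chi_square, tolerance = 1e-12)
  # permutation oracle for the p-value
  n_perm <- 2000
  null_chi <- vapply(seq_len(n_perm), function(i) {
    log_rank_test(times, events, sample(groups))$chi_square
  }, 0)
  p_perm <- mean(null_chi >= lr$chi_square)
  expect_lt(abs(p_perm - lr$p), 3 * sqrt(0.25 / n_perm) + 0.02)
})

test_that("Cox estimate maximizes the Breslow partial likelihood", {
  # symmetric two-group data -> beta = 0
  t0 <- c(1, 2, 3, 4); e0 <- c(1, 1, 1, 1)
  fit0 <- cox_univariable(c(t0, t0), c(e0, e0),
                          rep(c(0, 1), each = 4))
  expect_equal(fit0$beta, 0, tolerance = 1e-8)
  expect_equal(fit0$hr, 1, tolerance = 1e-8)
  # grid-search oracle on a small untied dataset
  times <- c(1, 3, 5, 7); events <- c(1, 1, 1, 0); x <- c(1, 0, 1, 0)
  fit <- cox_univariable(times, events, x)
  grid <- seq(-5, 5, by = 1e-3)
  ll <- vapply(grid, breslow_loglik, 0, times = times, events = events,
               x = x)
  expect_equal(fit$beta, grid[which.max(ll)], tolerance = 2e-3)
  expect_true(fit$converged)
  expect_error(cox_univariable(times, events, rep(1, 4)), "constant")
})

test_that("monotone likelihood is flagged, not silent", {
  # perfect separation: high covariate always fails first
  times <- c(1, 2, 3, 10, 11, 12)
  events <- c(1, 1, 1, 1, 1, 1)
  x <- c(1, 1, 1, 0, 0, 0)
  fit <- cox_univariable(times, events, x)
  expect_false(fit$converged)
})

test_that("Harrell's C matches exhaustive pair enumeration", {
  # worked case: times {1, 2+, 3}, risks {3, 1, 2}
  res <- harrell_c(c(1, 2, 3), c(1, 0, 1), c(3, 1, 2))
  expect_equal(res$comparable, 2)
  expect_equal(res$concordant, 2)
  expect_equal(res$c_index, 1)
  # perfect anti-ordering, all events
  res2 <- harrell_c(1:5, rep(1, 5), 5:1)
  expect_equal(res2$c_index, 1)
  # all risks tied -> 0.5
  res3 <- harrell_c(1:5, rep(1, 5), rep(2, 5))
  expect_equal(res3$c_index, 0.5)
  expect_equal(res3$tied, res3$comparable)
  set.seed(64)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    times <- sample(1:20, n, replace = TRUE)
    events <- rbinom(n, 1, 0.7)
    risk <- sample(1:5, n, replace = TRUE)
    if (sum(events) == 0) events[1] <- 1
    got <- harrell_c(times, events, risk)
    ref <- c_index_enumeration(times, events, risk)
    expect_equal(got$c_index, ref$c_index)
    expect_equal(got$comparable, ref$comparable)
    expect_equal(got$concordant, ref$concordant)
    expect_equal(got$discordant, ref$discordant)
    expect_equal(got$tied, ref$tied)
  }
  expect_error(harrell_c(c(1, 1), c(1, 1), c(1, 2)), "comparable")
})
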