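# Small in-code fixtures shared across test files.

# genes x samples matrix with deterministic names
toy_matrix <- function(values, n_genes, n_samples,
                       genes = paste0("g", seq_len(n_genes)),
                       samples = paste0("s", seq_len(n_samples))) {
  matrix(values, nrow = n_genes, ncol = n_samples,
         dimnames = list(genes, samples))
}

# a valid minimal cohort data frame
toy_cohort <- function(n = 6, marker = seq_len(n), time = seq_len(n) + 1,
                       event = rep_len(c(1, 0), n),
                       stage = rep_len(c(0, 1), n)) {
  data.frame(sample_id = paste0("s", seq_len(n)), time = time,
             event = event, stage_group = stage, marker = marker,
             stringsAsFactors = FALSE)
}

# write lines to a temp file, return path
tmp_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# brute-force ES oracle: recompute both cumulative distributions at every
# position, independent of the incremental implementation
es_bruteforce <- function(metric, hit, weight_exponent = 1) {
  N <- length(metric)
  m <- sum(hit)
  w <- abs(metric)^weight_exponent
  dev <- vapply(seq_len(N), function(i) {
    ph <- sum(w[seq_len(i)][hit[seq_len(i)]]) / sum(w[hit])
    pm <- sum(!hit[seq_len(i)]) / (N - m)
    ph - pm
  }, 0)
  i <- which.max(abs(dev))
  # tie toward the positive deviation, as the implementation states
  cand <- dev[abs(dev) == abs(dev[i])]
  if (any(cand > 0)) max(cand) else dev[i]
}

# exhaustive Harrell C oracle over all pairs
c_index_enumeration <- function(times, events, risk) {
  conc <- disc <- tied <- 0
  n <- length(times)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (times[i] == times[j]) {
        # orderable only when exactly one of the pair has the event: the
        # death precedes the censoring at the same recorded time
        if (events[i] + events[j] != 1) next
        lo <- if (events[i] == 1) i else j
        hi <- if (events[i] == 1) j else i
      } else {
        lo <- if (times[i] < times[j]) i else j
        hi <- if (times[i] < times[j]) j else i
        if (events[lo] != 1) next
      }
      if (risk[lo] > risk[hi]) conc <- conc + 1
      else if (risk[lo] < risk[hi]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  list(c_index = (conc + 0.5 * tied) / (conc + disc + tied),
       comparable = conc + disc + tied, concordant = conc,
       discordant = disc, tied = tied)
}

# hand-rolled Breslow partial log-likelihood for a single covariate
breslow_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    d <- which(times == t & events == 1)
    atrisk <- which(times >= t)
    ll <- ll + sum(beta * x[d]) -
      length(d) * log(sum(exp(beta * x[atrisk])))
  }
  ll
}
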