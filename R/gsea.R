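#' Rank genes by Pearson correlation with a cohort marker
#'
#' Computes, for every gene, the Pearson correlation between its cohort
#' expression and the continuous marker, and returns genes sorted by
#' descending correlation. Ties are broken lexicographically by gene symbol
#' so the ranking is bit-reproducible. Zero-variance genes get `r = 0` with
#' a warning.
#'
#' @param expr Log2 expression matrix (genes x samples).
#' @param cohort Cohort table with `sample_id` and `marker`; at least 3
#'   samples must be shared with `expr`.
#' @return Data frame with columns `gene_id`, `metric` (the correlation),
#'   ordered by descending metric.
#' @export
rank_by_marker_correlation <- function(expr, cohort) {
  cohort <- as_cohort_table(cohort)
  shared <- intersect(colnames(expr), cohort$sample_id)
  if (length(shared) < 3L) stop("need at least 3 shared samples, got ",
                                length(shared))
  marker <- cohort$marker[match(shared, cohort$sample_id)]
  x <- expr[, shared, drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  r <- rep(0, nrow(x))
  ok <- sds > 0 & stats::sd(marker) > 0
  if (any(!ok)) warning(sum(!ok), " zero-variance gene(s); r set to 0")
  r[ok] <- as.numeric(stats::cor(t(x[ok, , drop = FALSE]), marker))
  ord <- order(-r, rownames(x))
  data.frame(gene_id = rownames(x)[ord], metric = r[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The classic GSEA running-sum statistic. Walking down the ranked list, the
#' hit distribution increments by `|metric|^weight_exponent` (normalized by
#' the total over hits) at set members and the miss distribution by
#' `1/(N - m)` elsewhere; the enrichment score is the signed maximum
#' deviation of `P_hit - P_miss`. Exact ties in `|deviation|` are broken
#' toward the positive deviation (logged via message).
#'
#' With `weight_exponent = 0` the statistic reduces to the unweighted
#' Kolmogorov-Smirnov form.
#'
#' @param ranked Data frame from [rank_by_marker_correlation()] (columns
#'   `gene_id`, `metric`).
#' @param set Character vector of gene symbols; must hit at least one and
#'   not all ranked genes.
#' @param weight_exponent Non-negative weighting power (default 1).
#' @return A list with `es` and `profile` (data frame `position`,
#'   `gene_id`, `hit`, `deviation`).
#' @export
enrichment_score <- function(ranked, set, weight_exponent = 1) {
  stopifnot(weight_exponent >= 0)
  hit <- ranked$gene_id %in% set
  m <- sum(hit); N <- length(hit)
  if (m == 0L) stop("gene set has no members in the ranked list")
  if (m == N) stop("gene set covers the entire ranked list (no misses)")
  w <- abs(ranked$metric)^weight_exponent
  wh <- sum(w[hit])
  p_hit <- if (wh > 0) cumsum(ifelse(hit, w, 0)) / wh else cumsum(hit) / m
  p_miss <- cumsum(!hit) / (N - m)
  dev <- p_hit - p_miss
  i_pos <- which.max(dev); i_neg <- which.min(dev)
  if (abs(dev[i_neg]) > dev[i_pos]) {
    es <- dev[i_neg]
  } else {
    if (abs(dev[i_neg]) == dev[i_pos] && dev[i_neg] < 0) {
      message("tie in |deviation|; keeping the positive deviation")
    }
    es <- dev[i_pos]
  }
  list(es = es,
       profile = data.frame(position = seq_len(N), gene_id = ranked$gene_id,
                            hit = hit, deviation = dev,
                            row.names = NULL, stringsAsFactors = FALSE))
}

#' Permutation p-value and normalized enrichment score
#'
#' Builds a null distribution for the enrichment score and reports
#' `p_perm = (1 + #\{same-sign null |ES| >= |ES_obs|\}) / (1 + n_perm)` and
#' `nes = ES_obs / mean(|ES_null| of the same sign)`.
#'
#' Two nulls are offered. `"gene"` (default) permutes gene labels: each
#' permutation scores a random set of the same size against the fixed
#' ranking. `"sample"` shuffles the cohort marker and re-ranks the genes
#' before scoring, which requires `expr` and `cohort`.
#'
#' @param ranked Data frame (`gene_id`, `metric`); for `mode = "sample"` it
#'   is recomputed internally from `expr` and `cohort`.
#' @param set Character vector of gene symbols.
#' @param n_perm Number of permutations (>= 100).
#' @param mode `"gene"` or `"sample"`.
#' @param seed Integer RNG seed (stored in the result).
#' @param weight_exponent Passed to [enrichment_score()].
#' @param set_name Label for the result.
#' @param expr,cohort Required for `mode = "sample"`.
#' @return A list with `set_name`, `es`, `nes`, `p_perm`, `n_perm`, `seed`,
#'   `null_es`.
#' @export
permutation_p <- function(ranked, set, n_perm = 1000,
                          mode = c("gene", "sample"), seed = 1L,
                          weight_exponent = 1, set_name = "set",
                          expr = NULL, cohort = NULL) {
  mode <- match.arg(mode)
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (mode == "sample" && (is.null(expr) || is.null(cohort))) {
    stop("sample-label mode needs expr and cohort to re-rank")
  }
  obs <- enrichment_score(ranked, set, weight_exponent)$es
  m <- sum(ranked$gene_id %in% set)
  N <- nrow(ranked)
  set.seed(as.integer(seed))
  null_es <- if (mode == "gene") {
    w <- abs(ranked$metric)^weight_exponent
    vapply(seq_len(n_perm), function(i) {
      es_from_hits(sample.int(N, m), w, N)
    }, 0)
  } else {
    cohort <- as_cohort_table(cohort)
    vapply(seq_len(n_perm), function(i) {
      sh <- cohort
      sh$marker <- sample(sh$marker)
      enrichment_score(rank_by_marker_correlation(expr, sh),
                       set, weight_exponent)$es
    }, 0)
  }
  same <- null_es * sign(obs) > 0
  if (!any(same)) {
    warning("no same-sign null enrichment scores; p floored at 1/(1+n_perm)")
    p <- 1 / (1 + n_perm)
    nes <- NA_real_
  } else {
    p <- (1 + sum(same & abs(null_es) >= abs(obs))) / (1 + n_perm)
    nes <- obs / mean(abs(null_es[same]))
  }
  list(set_name = set_name, es = obs, nes = nes, p_perm = p,
       n_perm = n_perm, seed = as.integer(seed), null_es = null_es)
}

# ES for a hit-index vector against fixed weights; same walk as
# enrichment_score but without building the profile (hot loop of the
# gene-label null).
es_from_hits <- function(hit_idx, w, N) {
  hit <- logical(N); hit[hit_idx] <- TRUE
  wh <- sum(w[hit])
  p_hit <- if (wh > 0) cumsum(ifelse(hit, w, 0)) / wh
           else cumsum(hit) / length(hit_idx)
  dev <- p_hit - cumsum(!hit) / (N - length(hit_idx))
  mx <- max(dev); mn <- min(dev)
  if (abs(mn) > mx) mn else mx
}
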