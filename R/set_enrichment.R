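#' Gene-set Z-scores by Stouffer combination
#'
#' For each gene set, combines the per-gene standardized effects of a
#' differential table into a signed set-level Z-score,
#' `z_set = sum(z_g over members in the universe) / sqrt(m)`, where `m` is
#' the number of set members found in the experiment's gene universe. A
#' positive score means overall enrichment (members shifted up), a negative
#' score depletion. Sets with fewer than `min_size` members in the universe
#' are dropped with a message.
#'
#' @param diff Data frame from [differential_table()] (needs `gene_id`, `z`).
#' @param sets Named list of character vectors ([parse_gmt()]).
#' @param min_size Minimum members-in-universe per set (default 5).
#' @return Data frame with columns `set_name`, `z_set`, `m`.
#' @export
set_z_scores <- function(diff, sets, min_size = 5) {
  stopifnot(nrow(diff) > 0L, is.list(sets), length(sets) > 0L)
  z <- stats::setNames(diff$z, diff$gene_id)
  res <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], names(z))
    m <- length(members)
    if (m < min_size) return(NULL)
    data.frame(set_name = nm, z_set = sum(z[members]) / sqrt(m), m = m,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(res, is.null, TRUE))
  if (dropped == length(sets)) stop("no usable sets: all below min_size ",
                                    "in this universe")
  if (dropped > 0L) message("dropped ", dropped,
                            " set(s) below min_size = ", min_size)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compare set-level Z vectors between two experiments
#'
#' Pairs the two tables on common set names and reports the Pearson
#' correlation with its two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. A
#' negative correlation is the expected pattern when the two experiments
#' perturb the same regulator in opposite directions (knockdown vs.
#' over-expression).
#'
#' @param a,b Data frames from [set_z_scores()].
#' @return A list with `set_names`, `z_a`, `z_b`, `n`, `r`, `p`.
#' @export
compare_z_vectors <- function(a, b) {
  common <- intersect(a$set_name, b$set_name)
  if (length(common) < 3L) stop("need at least 3 common sets, got ",
                                length(common))
  za <- a$z_set[match(common, a$set_name)]
  zb <- b$z_set[match(common, b$set_name)]
  if (stats::sd(za) == 0 || stats::sd(zb) == 0) {
    stop("zero variance in a Z vector; correlation undefined")
  }
  ct <- stats::cor.test(za, zb, method = "pearson", alternative = "two.sided")
  list(set_names = common, z_a = za, z_b = zb, n = length(common),
       r = unname(ct$estimate), p = ct$p.value)
}

#' Reciprocal top-N overlap test between two experiments
#'
#' Takes the top `n` genes of each differential table, ranked by effect in
#' the requested direction over the common gene universe, and tests the
#' overlap against the one-sided hypergeometric tail `P(X >= k)` with
#' `X ~ Hypergeom(N, n, n)` — Fisher's exact test for a 2x2 table with both
#' margins fixed at `n`.
#'
#' @param diff_a,diff_b Differential tables sharing a gene universe of size
#'   `N >= 2n`.
#' @param n Number of top genes to take from each table.
#' @param direction_a,direction_b `"up"` (largest effects) or `"down"`
#'   (smallest effects).
#' @return A list with `overlap`, `n`, `universe` (N), `expected`
#'   (`n^2/N`), and `p`.
#' @export
top_n_overlap_test <- function(diff_a, diff_b, n,
                               direction_a = c("up", "down"),
                               direction_b = c("up", "down")) {
  direction_a <- match.arg(direction_a)
  direction_b <- match.arg(direction_b)
  universe <- intersect(diff_a$gene_id, diff_b$gene_id)
  N <- length(universe)
  if (n > N) stop("n (", n, ") exceeds common universe size (", N, ")")
  if (N < 2L * n) stop("common universe (", N, ") smaller than 2n")
  top_genes <- function(diff, direction) {
    d <- diff[diff$gene_id %in% universe, ]
    eff <- if (direction == "up") -d$effect else d$effect
    d$gene_id[order(eff, d$gene_id)][seq_len(n)]
  }
  k <- length(intersect(top_genes(diff_a, direction_a),
                        top_genes(diff_b, direction_b)))
  p <- stats::phyper(k - 1, n, N - n, n, lower.tail = FALSE)
  list(overlap = k, n = n, universe = N, expected = n^2 / N, p = p)
}

#' Select significantly activated and depleted sets
#'
#' @param zt Data frame from [set_z_scores()].
#' @param cutoff Positive Z threshold (the conventional screen uses 3).
#' @return A list with `activated` (names with `z_set > cutoff`) and
#'   `depleted` (`z_set < -cutoff`), each sorted by `|z_set|` descending.
#' @export
select_significant_sets <- function(zt, cutoff = 3) {
  stopifnot(cutoff > 0)
  pick <- function(idx) {
    nm <- zt$set_name[idx]
    nm[order(-abs(zt$z_set[idx]), nm)]
  }
  list(activated = pick(which(zt$z_set > cutoff)),
       depleted = pick(which(zt$z_set < -cutoff)))
}
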