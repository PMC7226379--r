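#' Per-gene differential statistics for a two-group perturbation
#'
#' For each gene, computes the mean log2 difference between treated and
#' control replicates, the across-gene standardized effect (Z-score), and a
#' two-sided p-value from Welch's unequal-variance t-test
#' (Welch-Satterthwaite degrees of freedom). The Z standardizes each gene's
#' effect against the distribution of effects over all genes, so the vector
#' `z` has mean 0 and sample standard deviation 1 by construction.
#'
#' Degenerate genes with zero within-group variance in both groups get the
#' limiting p-value (0 if the means differ, 1 if they are equal), with a
#' warning.
#'
#' @param expr Numeric log2 expression matrix (genes x samples) with sample
#'   colnames.
#' @param treated,control Disjoint character vectors of sample ids, each of
#'   length >= 2 and present in `colnames(expr)`.
#' @param t_method `"welch"` (default) or `"pooled"` (classical equal-variance
#'   Student t). Provided because small-replicate array studies rarely state
#'   which was used.
#' @param z_mode `"effect"` (default): standardize the per-gene effects
#'   across genes. `"intensity"`: standardize each sample's intensities
#'   across genes first, then take the difference of standardized group
#'   means and re-standardize. The two readings of "expression values in
#'   Z-score" differ only by an affine map of the effect vector.
#' @return A data frame with columns `gene_id`, `effect`, `z`, `p`,
#'   `n_treated`, `n_control`.
#' @examples
#' m <- matrix(rnorm(60), nrow = 10,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
#' differential_table(m, treated = c("s1", "s2", "s3"),
#'                    control = c("s4", "s5", "s6"))
#' @export
differential_table <- function(expr, treated, control,
                               t_method = c("welch", "pooled"),
                               z_mode = c("effect", "intensity")) {
  t_method <- match.arg(t_method)
  z_mode <- match.arg(z_mode)
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (length(intersect(treated, control)) > 0L) {
    stop("treated and control sample sets must be disjoint")
  }
  for (grp in list(treated = treated, control = control)) {
    absent <- setdiff(grp, colnames(expr))
    if (length(absent)) stop("sample id(s) not in matrix: ",
                             paste(absent, collapse = ", "))
  }
  if (length(treated) < 2L || length(control) < 2L) {
    stop("each group needs at least 2 replicates")
  }
  xt <- expr[, treated, drop = FALSE]
  xc <- expr[, control, drop = FALSE]
  n1 <- ncol(xt); n2 <- ncol(xc)
  m1 <- rowMeans(xt); m2 <- rowMeans(xc)
  v1 <- rowSums((xt - m1)^2) / (n1 - 1)
  v2 <- rowSums((xc - m2)^2) / (n2 - 1)
  effect <- m1 - m2

  if (t_method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tstat <- effect / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tstat <- effect / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(effect))
  }
  p <- 2 * stats::pt(-abs(tstat), df)

  degen <- v1 == 0 & v2 == 0
  if (any(degen)) {
    warning(sum(degen), " gene(s) with zero variance in both groups; ",
            "p set to degenerate limit")
    p[degen] <- ifelse(effect[degen] == 0, 1, 0)
  }

  z <- switch(z_mode,
    effect = standardize(effect),
    intensity = {
      zi <- scale(expr[, c(treated, control), drop = FALSE])
      standardize(rowMeans(zi[, treated, drop = FALSE]) -
                  rowMeans(zi[, control, drop = FALSE]))
    })

  data.frame(gene_id = rownames(expr), effect = effect, z = as.numeric(z),
             p = p, n_treated = n1, n_control = n2,
             row.names = NULL, stringsAsFactors = FALSE)
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize: zero spread")
  (x - mean(x)) / s
}

#' Relative expression by the 2^-ddCt method
#'
#' Standard qRT-PCR relative quantification against a reference gene
#' (e.g. cyclophilin A) and a calibrator sample:
#' `ddCt = (Ct_target_sample - Ct_ref_sample) -
#' (Ct_target_calibrator - Ct_ref_calibrator)` and the fold change is
#' `2^-ddCt`.
#'
#' @param ct_target_sample,ct_ref_sample Ct values of the target and
#'   reference gene in the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator Ct values in the calibrator.
#' @return Fold change relative to the calibrator (vectorized).
#' @export
ddct_relative_expression <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_calibrator, ct_ref_calibrator) {
  cts <- cbind(ct_target_sample, ct_ref_sample,
               ct_target_calibrator, ct_ref_calibrator)
  if (!all(is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}

#' Write a differential table as TSV
#'
#' @param diff Data frame from [differential_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential_table <- function(diff, path) {
  utils::write.table(diff, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
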