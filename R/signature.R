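#' Derive a pathway-restricted, cohort-validated gene signature
#'
#' Two-stage derivation used for the cell-cycle (G1) signature. Stage 1
#' intersects a pathway gene set with the genes significantly changed in
#' BOTH perturbation experiments (`p < p_cut` in the knockdown table and in
#' the over-expression table). Stage 2 keeps candidates whose cohort
#' expression correlates with the continuous marker at `p < p_cut_corr`
#' (Pearson). Genes negatively correlated with the marker become
#' `up_genes` and positively correlated genes become `down_genes`: the
#' marker-low state is the high-risk state, so genes that rise as the
#' marker falls carry the risk orientation.
#'
#' @param pathway_set Character vector of pathway gene symbols.
#' @param diff_kd,diff_exp Differential tables of the two perturbations.
#' @param expr_cohort Cohort log2 expression matrix.
#' @param cohort Cohort table (needs `sample_id`, `marker`).
#' @param p_cut Per-experiment significance threshold (default 0.05).
#' @param p_cut_corr Cohort-correlation threshold (default 0.01).
#' @param name Signature name.
#' @return A `signature_definition`: list with `name`, `up_genes`,
#'   `down_genes`, and a `provenance` record (thresholds, candidate genes,
#'   per-candidate correlations).
#' @export
derive_pathway_signature <- function(pathway_set, diff_kd, diff_exp,
                                     expr_cohort, cohort,
                                     p_cut = 0.05, p_cut_corr = 0.01,
                                     name = "pathway_signature") {
  cohort <- as_cohort_table(cohort)
  sig_kd <- diff_kd$gene_id[diff_kd$p < p_cut]
  sig_exp <- diff_exp$gene_id[diff_exp$p < p_cut]
  candidates <- intersect(pathway_set, intersect(sig_kd, sig_exp))
  if (length(candidates) == 0L) {
    stop("no candidate genes: pathway set does not intersect the ",
         "doubly-significant genes")
  }
  shared <- intersect(colnames(expr_cohort), cohort$sample_id)
  if (length(shared) < 3L) stop("need at least 3 shared cohort samples")
  marker <- cohort$marker[match(shared, cohort$sample_id)]
  candidates <- intersect(candidates, rownames(expr_cohort))
  corr <- lapply(candidates, function(g) {
    x <- expr_cohort[g, shared]
    if (stats::sd(x) == 0) return(data.frame(gene_id = g, r = 0, p = 1))
    ct <- stats::cor.test(x, marker, method = "pearson")
    data.frame(gene_id = g, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  corr <- do.call(rbind, corr)
  keep <- corr[corr$p < p_cut_corr, , drop = FALSE]
  if (nrow(keep) == 0L) {
    warning("no candidates survive the cohort-correlation filter")
  }
  sig <- signature_definition(
    name = name,
    up_genes = keep$gene_id[keep$r < 0],
    down_genes = keep$gene_id[keep$r > 0],
    provenance = list(method = "pathway_intersection_cohort_correlation",
                      p_cut = p_cut, p_cut_corr = p_cut_corr,
                      n_pathway = length(pathway_set),
                      n_candidates = length(candidates),
                      candidate_correlations = corr,
                      risk_orientation = "marker-low is high-risk"))
  sig
}

#' Derive a signature from a curated gene list and one knockdown experiment
#'
#' Filters a curated list (e.g. AKT downstream genes) on the knockdown
#' differential table: `up_genes` are curated genes with standardized effect
#' `z > z_cut` and `p < p_cut` (increased upon knockdown), `down_genes` those
#' with `z < -z_cut` and `p < p_cut`.
#'
#' @param curated_genes Non-empty character vector of gene symbols.
#' @param diff_kd Differential table of the knockdown experiment.
#' @param z_cut Standardized-effect threshold (default 2).
#' @param p_cut Significance threshold (default 0.05).
#' @param name Signature name.
#' @return A `signature_definition`; empty up/down lists are allowed, with
#'   a warning.
#' @export
derive_list_signature <- function(curated_genes, diff_kd, z_cut = 2,
                                  p_cut = 0.05, name = "list_signature") {
  stopifnot(length(curated_genes) > 0L)
  d <- diff_kd[diff_kd$gene_id %in% curated_genes, , drop = FALSE]
  up <- d$gene_id[d$z > z_cut & d$p < p_cut]
  down <- d$gene_id[d$z < -z_cut & d$p < p_cut]
  if (length(up) + length(down) == 0L) {
    warning("no curated genes pass the |z| and p filters; empty signature")
  }
  signature_definition(
    name = name, up_genes = up, down_genes = down,
    provenance = list(method = "curated_list_threshold",
                      z_cut = z_cut, p_cut = p_cut,
                      n_curated = length(curated_genes)))
}

#' Construct a signature definition
#'
#' @param name Signature name.
#' @param up_genes,down_genes Disjoint character vectors; their union may be
#'   empty only during derivation (a warning is the caller's duty).
#' @param provenance Arbitrary derivation record.
#' @return An object of class `signature_definition`.
#' @export
signature_definition <- function(name, up_genes, down_genes,
                                 provenance = list()) {
  up_genes <- as.character(up_genes); down_genes <- as.character(down_genes)
  if (anyDuplicated(up_genes) || anyDuplicated(down_genes)) {
    stop("duplicate genes within a signature side")
  }
  if (length(intersect(up_genes, down_genes)) > 0L) {
    stop("up and down gene lists must be disjoint")
  }
  structure(list(name = name, up_genes = up_genes, down_genes = down_genes,
                 provenance = provenance),
            class = "signature_definition")
}

#' @export
print.signature_definition <- function(x, ...) {
  cat("Signature '", x$name, "': ", length(x$up_genes), " up / ",
      length(x$down_genes), " down genes\n", sep = "")
  invisible(x)
}

#' Write a signature as a two-line GMT fragment
#'
#' Serializes the up and down lists as `<name>_UP` and `<name>_DOWN` sets.
#'
#' @param sig A `signature_definition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_gmt <- function(sig, path) {
  sets <- list(sig$up_genes, sig$down_genes)
  names(sets) <- paste0(sig$name, c("_UP", "_DOWN"))
  sets <- sets[lengths(sets) > 0]
  write_gmt(sets, path)
}

#' Per-sample signature score: difference of geometric means
#'
#' For each sample, the score is the mean log2 expression over the up genes
#' minus the mean over the down genes. Because the inputs are log2-scale,
#' this equals the log2 ratio of the geometric means on the linear scale —
#' the standard "difference of geometric means" score. With
#' `scale = "linear"` the input is instead treated as raw intensities:
#' geometric means are taken on the values themselves and the score is
#' their log2 ratio (sensitivity-analysis mode).
#'
#' @param expr Expression matrix (genes x samples).
#' @param sig A `signature_definition`; each side must have at least one
#'   gene present in `expr` (missing genes are reported via message).
#' @param scale `"log2"` (default) or `"linear"`.
#' @return Data frame with columns `sample_id`, `score`, `signature`.
#' @export
signature_score <- function(expr, sig, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  up <- intersect(sig$up_genes, rownames(expr))
  down <- intersect(sig$down_genes, rownames(expr))
  if (length(up) == 0L) stop("no up-signature genes present in the matrix")
  if (length(down) == 0L) stop("no down-signature genes present in the matrix")
  n_missing <- length(sig$up_genes) + length(sig$down_genes) -
    length(up) - length(down)
  if (n_missing > 0L) message(n_missing, " signature gene(s) absent from ",
                              "the matrix")
  side_mean <- function(genes) {
    x <- expr[genes, , drop = FALSE]
    if (scale == "linear") {
      if (any(x <= 0)) stop("linear-scale scoring needs positive values")
      log2(exp(colMeans(log(x))))
    } else {
      colMeans(x)
    }
  }
  score <- side_mean(up) - side_mean(down)
  data.frame(sample_id = colnames(expr), score = as.numeric(score),
             signature = sig$name, row.names = NULL, stringsAsFactors = FALSE)
}

#' Unsupervised two-group clustering of samples
#'
#' Average-linkage hierarchical clustering of samples restricted to a gene
#' subset, with distance `1 - Pearson correlation` between sample profiles;
#' the tree is cut into exactly two clusters. Cluster labels are oriented so
#' that cluster 2 is the one with the higher mean expression of the
#' up-oriented genes.
#'
#' @param expr Expression matrix; at least 4 samples.
#' @param genes Gene subset (>= 2 present in `expr`).
#' @param up_genes Genes defining the orientation of cluster 2; defaults to
#'   all of `genes`.
#' @return Named integer vector (1 or 2) per sample.
#' @export
cluster_two_groups <- function(expr, genes, up_genes = genes) {
  genes <- intersect(genes, rownames(expr))
  if (length(genes) < 2L) stop("need at least 2 genes present in the matrix")
  if (ncol(expr) < 4L) stop("need at least 4 samples")
  x <- expr[genes, , drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(x))
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = 2)
  up_genes <- intersect(up_genes, genes)
  if (length(up_genes) == 0L) up_genes <- genes
  up_mean <- tapply(colMeans(expr[up_genes, , drop = FALSE]), cl, mean)
  if (up_mean[["1"]] > up_mean[["2"]]) cl <- 3L - cl
  cl
}
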