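#' Default pipeline configuration
#'
#' Thresholds of the analysis chain: per-experiment significance 0.05,
#' cohort-correlation significance 0.01, standardized-effect cutoff 2,
#' set-level Z cutoff 3, minimum set size 5, reciprocal top-N 1000, and the
#' GSEA settings. Any field can be overridden via `...`; input paths (for a
#' run on real files) or `simulate = TRUE` (for the synthetic demo) select
#' the data source.
#'
#' @param ... Overrides for the defaults listed above, plus optional paths
#'   `expr_kd`, `expr_exp`, `gmt`, `expr_cohort`, `clinical`,
#'   `curated_genes`, group definitions `kd_treated`, `kd_control`,
#'   `exp_treated`, `exp_control`, and `sim` (a [simulation_config()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(simulate = TRUE, sim = NULL,
              expr_kd = NULL, expr_exp = NULL, gmt = NULL,
              expr_cohort = NULL, clinical = NULL, curated_genes = NULL,
              kd_treated = NULL, kd_control = NULL,
              exp_treated = NULL, exp_control = NULL,
              p_cut = 0.05, p_cut_corr = 0.01, z_cut = 2,
              set_z_cutoff = 3, min_set_size = 5, top_n = 1000,
              gsea_weight = 1, gsea_n_perm = 1000, gsea_mode = "gene",
              seed = 7L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown pipeline option(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$p_cut > 0, cfg$p_cut_corr > 0, cfg$z_cut > 0,
            cfg$set_z_cutoff > 0, cfg$min_set_size > 0, cfg$top_n > 0)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a YAML or JSON file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis chain
#'
#' Executes differential statistics for both perturbations, set-level Z
#' enrichment and the cross-experiment comparison, the reciprocal top-N
#' overlap test, GSEA of the derived signature against the cohort marker
#' ranking, signature derivation (pathway-based and curated-list-based) and
#' scoring, median dichotomization, the composite prognostic score, and the
#' survival statistics (Kaplan-Meier per stratum, log-rank across strata,
#' univariable Cox on the composite score, Harrell's C per factor and for
#' the composite). All intermediate tables, a machine-readable
#' `summary.json`, and a run log are written under `out_dir`.
#'
#' With `config$simulate = TRUE` (the default demo) all inputs come from the
#' synthetic generators; otherwise they are read from the configured paths.
#'
#' @param config A [pipeline_config()] (or a path readable by
#'   [read_pipeline_config()]).
#' @param out_dir Output directory (created if missing).
#' @param verbose Log progress to stderr.
#' @return The summary list, invisibly; on disk: TSV tables, `summary.json`,
#'   `run.log`.
#' @export
run_full <- function(config, out_dir, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    if (verbose) message(msg)
  }
  log_line("sigprog ", as.character(utils::packageVersion("sigprog")),
           " run_full; seed=", config$seed)

  stage <- function(name, expr) {
    log_line("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- stage("inputs", pipeline_inputs(config))
  summary <- list(seed = config$seed,
                  thresholds = config[c("p_cut", "p_cut_corr", "z_cut",
                                        "set_z_cutoff", "min_set_size",
                                        "top_n")])

  diff_kd <- stage("differential_kd",
                   differential_table(inputs$kd$expr, inputs$kd$treated,
                                      inputs$kd$control))
  diff_exp <- stage("differential_exp",
                    differential_table(inputs$exp$expr, inputs$exp$treated,
                                       inputs$exp$control))
  write_differential_table(diff_kd, file.path(out_dir, "differential_kd.tsv"))
  write_differential_table(diff_exp, file.path(out_dir, "differential_exp.tsv"))

  enr <- stage("set_enrichment", {
    zt_kd <- set_z_scores(diff_kd, inputs$sets, config$min_set_size)
    zt_exp <- set_z_scores(diff_exp, inputs$sets, config$min_set_size)
    cmp <- compare_z_vectors(zt_kd, zt_exp)
    n_top <- min(config$top_n, floor(length(
      intersect(diff_kd$gene_id, diff_exp$gene_id)) / 2))
    ov <- top_n_overlap_test(diff_kd, diff_exp, n_top, "up", "down")
    list(zt_kd = zt_kd, zt_exp = zt_exp, cmp = cmp, ov = ov,
         sig_kd = select_significant_sets(zt_kd, config$set_z_cutoff))
  })
  utils::write.table(enr$zt_kd, file.path(out_dir, "set_z_kd.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(enr$zt_exp, file.path(out_dir, "set_z_exp.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$set_z_comparison <- list(n = enr$cmp$n, r = enr$cmp$r, p = enr$cmp$p)
  summary$top_n_overlap <- enr$ov[c("overlap", "n", "universe", "p")]
  summary$activated_sets_kd <- as.list(enr$sig_kd$activated)

  sigs <- stage("signatures", {
    cc <- derive_pathway_signature(inputs$pathway_set, diff_kd, diff_exp,
                                   inputs$cohort_expr, inputs$cohort,
                                   p_cut = config$p_cut,
                                   p_cut_corr = config$p_cut_corr,
                                   name = "cell_cycle")
    akt <- derive_list_signature(inputs$curated_genes, diff_kd,
                                 z_cut = config$z_cut, p_cut = config$p_cut,
                                 name = "akt")
    list(cc = cc, akt = akt)
  })
  write_signature_gmt(sigs$cc, file.path(out_dir, "signature_cell_cycle.gmt"))
  write_signature_gmt(sigs$akt, file.path(out_dir, "signature_akt.gmt"))
  summary$signatures <- lapply(sigs, function(s) {
    list(up = length(s$up_genes), down = length(s$down_genes))
  })

  gsea_res <- stage("gsea", {
    ranked <- rank_by_marker_correlation(inputs$cohort_expr, inputs$cohort)
    sides <- list(akt_up = sigs$akt$up_genes, akt_down = sigs$akt$down_genes)
    sides <- sides[lengths(sides) > 0]
    if (length(sides) == 0L) sides <- list(pathway = inputs$pathway_set)
    lapply(names(sides), function(nm) {
      permutation_p(ranked, sides[[nm]], n_perm = config$gsea_n_perm,
                    mode = config$gsea_mode, seed = config$seed,
                    weight_exponent = config$gsea_weight, set_name = nm,
                    expr = inputs$cohort_expr, cohort = inputs$cohort)
    })
  })
  summary$gsea <- lapply(gsea_res, function(r) {
    r[c("set_name", "es", "nes", "p_perm", "n_perm")]
  })

  surv <- stage("survival", {
    co <- inputs$cohort
    akt_scores <- signature_score(inputs$cohort_expr, sigs$akt)$score
    cc_scores <- signature_score(inputs$cohort_expr, sigs$cc)$score
    marker_low <- 1L - dichotomize_by_median(co$marker)$high
    akt_high <- dichotomize_by_median(akt_scores)$high
    cc_high <- dichotomize_by_median(cc_scores)$high
    cs <- composite_score(co$stage_group, marker_low, akt_high, cc_high)
    strata <- split(seq_len(nrow(co)), cs$label)
    km <- lapply(strata[lengths(strata) > 0], function(i) {
      km_estimate(co$time[i], co$event[i])
    })
    lr <- if (length(unique(cs$score)) >= 2)
      log_rank_test(co$time, co$event, cs$score) else NULL
    cox <- cox_univariable(co$time, co$event, cs$score)
    cvals <- list(stage = co$stage_group, marker_low = marker_low,
                  akt_high = akt_high, cc_high = cc_high,
                  composite = cs$score)
    cidx <- lapply(cvals, function(v) {
      if (stats::sd(v) == 0) return(NULL)
      harrell_c(co$time, co$event, v)$c_index
    })
    list(score = cs, km = km, lr = lr, cox = cox, cidx = cidx,
         table = data.frame(sample_id = co$sample_id,
                            akt_score = akt_scores, cc_score = cc_scores,
                            marker_low = marker_low, akt_high = akt_high,
                            cc_high = cc_high, score = cs$score,
                            stringsAsFactors = FALSE))
  })
  utils::write.table(surv$table, file.path(out_dir, "prognostic_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$strata <- paste("score", 0:4)
  summary$strata_counts <- as.list(as.integer(table(surv$score$label)))
  names(summary$strata_counts) <- levels(surv$score$label)
  if (!is.null(surv$lr)) {
    summary$log_rank <- surv$lr[c("chi_square", "df", "p")]
  }
  summary$cox_composite <- surv$cox[c("beta", "hr", "se", "wald_p",
                                      "converged")]
  summary$c_index <- surv$cidx[!vapply(surv$cidx, is.null, TRUE)]
  summary$km_median <- lapply(surv$km, km_median)

  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, null = "null")
  writeLines(json, file.path(out_dir, "summary.json"), useBytes = TRUE)
  log_line("done")
  invisible(summary)
}

# Resolve pipeline inputs: synthetic demo or files on disk.
pipeline_inputs <- function(config) {
  if (isTRUE(config$simulate)) {
    sim_cfg <- config$sim
    if (is.null(sim_cfg)) sim_cfg <- simulation_config(seed = config$seed)
    pair <- simulate_perturbation_pair(sim_cfg)
    cohort_sim <- simulate_patient_cohort(sim_cfg)
    # gene-set collection: planted sets plus random decoys for context
    sets <- pair$sets
    set.seed(sim_cfg$seed + 3L)
    g <- rownames(pair$kd$expr)
    for (i in seq_len(25)) {
      sets[[sprintf("SET_RANDOM_%02d", i)]] <- sample(g, 50)
    }
    # pathway set: planted cell-cycle-like signature genes plus decoys
    cc <- cohort_sim$signatures$cc
    pathway_set <- unique(c(cc$up_genes, cc$down_genes,
                            sample(setdiff(g, unlist(sets)), 26)))
    curated <- unique(c(cohort_sim$signatures$akt$up_genes,
                        cohort_sim$signatures$akt$down_genes,
                        sample(setdiff(g, pathway_set), 131)))
    list(kd = pair$kd, exp = pair$exp, sets = sets,
         cohort_expr = cohort_sim$expr, cohort = cohort_sim$cohort,
         pathway_set = pathway_set, curated_genes = curated,
         truth = list(pair = pair$truth, cohort = cohort_sim$truth))
  } else {
    need <- c("expr_kd", "expr_exp", "gmt", "expr_cohort", "clinical",
              "curated_genes", "kd_treated", "kd_control", "exp_treated",
              "exp_control")
    for (nm in need) {
      if (is.null(config[[nm]])) stop("missing pipeline input: ", nm)
    }
    for (nm in c("expr_kd", "expr_exp", "gmt", "expr_cohort", "clinical",
                 "curated_genes")) {
      if (!file.exists(config[[nm]])) {
        stop("input file not found (", nm, "): ", config[[nm]])
      }
    }
    sets <- parse_gmt(config$gmt)
    list(kd = list(expr = read_expression_matrix(config$expr_kd),
                   treated = config$kd_treated,
                   control = config$kd_control),
         exp = list(expr = read_expression_matrix(config$expr_exp),
                    treated = config$exp_treated,
                    control = config$exp_control),
         sets = sets,
         cohort_expr = read_expression_matrix(config$expr_cohort),
         cohort = read_clinical_table(config$clinical),
         pathway_set = sets[[1L]],
         curated_genes = read_gene_list(config$curated_genes),
         truth = NULL)
  }
}
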