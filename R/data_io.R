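#' sigprog: perturbation-derived gene signatures and composite prognostic scoring
#'
#' The package implements an analysis chain built around a continuous tumor
#' marker (an nc886-like noncoding RNA measured by qRT-PCR) in a surgical
#' cohort: per-gene differential statistics for paired knockdown and
#' over-expression perturbations, gene-set Z-score enrichment and its
#' comparison between the two experiments, weighted Kolmogorov-Smirnov
#' enrichment with a permutation null, derivation of up/down gene signatures,
#' per-sample signature scores, and a four-factor composite prognostic score
#' evaluated with Kaplan-Meier curves, the log-rank test, univariable Cox
#' regression, and Harrell's concordance index. A synthetic-data generator
#' produces inputs with the statistical structure the chain assumes.
#'
#' @section Conventions:
#' Expression matrices are numeric matrices (genes in rows, samples in
#' columns) of log2-scale values; gene identity is by symbol, case-sensitive.
#' Gene-set collections are named lists of character vectors (GMT dialect).
#' Clinical data are data frames validated by [read_clinical_table()] /
#' [as_cohort_table()].
#'
#' @name sigprog-package
#' @keywords internal
"_PACKAGE"

#' Parse a GMT gene-set file
#'
#' Reads a tab-separated GMT file in the MSigDB dialect: each line holds a set
#' name, a description, and one or more member gene symbols. Duplicate member
#' symbols within a line are collapsed to their first occurrence with a
#' warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (set members), with a
#'   `descriptions` attribute (named character vector) carrying the second
#'   GMT column.
#' @seealso [write_gmt()]
#' @export
parse_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("GMT parse error: line ", which(nf < 3L)[1L],
         " has fewer than 3 tab-separated fields")
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set names in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  desc <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  n_dup <- sum(vapply(members, anyDuplicated, 0L) > 0L)
  if (n_dup > 0L) {
    warning(n_dup, " gene set(s) contained duplicate member symbols; ",
            "collapsed to first occurrence")
    members <- lapply(members, function(m) m[!duplicated(m)])
  }
  if (any(lengths(members) == 0L)) stop("gene set with no members")
  names(members) <- nm
  names(desc) <- nm
  attr(members, "descriptions") <- desc
  members
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions;
#'   defaults to the `descriptions` attribute of `sets`, else `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a log2 expression matrix from TSV
#'
#' The first column holds gene symbols; the header row holds sample
#' identifiers. Duplicate gene symbols are resolved by keeping the row with
#' the highest mean value; rows containing missing values are dropped. Both
#' actions are reported via [message()].
#'
#' @param path Path to a tab-delimited file.
#' @param platform Free-text platform tag attached as the `platform`
#'   attribute.
#' @return A numeric matrix (genes x samples) with unique rownames, finite
#'   values, and attributes `platform` and `n_dropped` (count of rows dropped
#'   for missingness).
#' @export
read_expression_matrix <- function(path, platform = "") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("empty or column-less expression file: ", path)
  }
  genes <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  bad <- !is.na(vals) & vals != "NA" & vals != "" & is.na(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-numeric expression value at gene row ", idx[1L],
         " ('", genes[idx[1L]], "'), sample column '",
         colnames(vals)[idx[2L]], "'")
  }
  rownames(num) <- genes
  miss <- apply(num, 1L, anyNA)
  n_dropped <- sum(miss)
  if (n_dropped > 0L) {
    message("dropped ", n_dropped, " gene row(s) with missing values")
    num <- num[!miss, , drop = FALSE]
  }
  if (nrow(num) == 0L) stop("no complete gene rows in ", path)
  num <- collapse_duplicate_genes(num)
  if (!all(is.finite(num))) stop("non-finite expression values in ", path)
  structure(num, platform = platform, n_dropped = n_dropped)
}

# Keep, per duplicated symbol, the row with the highest mean (array-collapse
# convention); deterministic.
collapse_duplicate_genes <- function(mat) {
  if (!anyDuplicated(rownames(mat))) return(mat)
  dup_syms <- unique(rownames(mat)[duplicated(rownames(mat))])
  message("collapsed ", length(dup_syms),
          " duplicated gene symbol(s) by highest mean")
  means <- rowMeans(mat)
  keep <- tapply(seq_len(nrow(mat)), rownames(mat),
                 function(i) i[which.max(means[i])])
  mat[sort(unlist(keep, use.names = FALSE)), , drop = FALSE]
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: first column `gene_id`, then one
#' column per sample. Values are written with full precision so a round trip
#' is bit-identical.
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene_id = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read and validate a clinical cohort table
#'
#' Expects a CSV with columns `sample_id`, `time` (survival time in months,
#' strictly positive), `event` (0/1), `stage_group` (0 = TNM I-II,
#' 1 = TNM III-IV), and `marker` (continuous marker value, e.g. nc886
#' qRT-PCR). Extra columns are preserved.
#'
#' @param path Path to a CSV file.
#' @return A validated data frame (cohort table).
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_cohort_table(df)
}

#' Validate a cohort table
#'
#' Enforces the cohort invariants: required columns present, `time > 0`,
#' `event` in {0,1}, `stage_group` in {0,1}, finite numeric `marker`, unique
#' sample identifiers.
#'
#' @param df A data frame.
#' @return The validated data frame (numeric columns coerced).
#' @export
as_cohort_table <- function(df) {
  required <- c("sample_id", "time", "event", "stage_group", "marker")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("clinical table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("time", "event", "stage_group", "marker")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) stop("clinical table column '", col, "' has missing or ",
                       "non-numeric values")
    df[[col]] <- v
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id values")
  if (any(df$time <= 0)) stop("invalid field 'time': must be > 0")
  if (!all(df$event %in% c(0, 1))) stop("invalid field 'event': must be 0 or 1")
  if (!all(df$stage_group %in% c(0, 1))) {
    stop("invalid field 'stage_group': must be 0 or 1")
  }
  if (!all(is.finite(df$marker))) stop("invalid field 'marker': must be finite")
  df
}

#' Write a cohort table as CSV
#'
#' @param cohort A cohort table (validated data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(cohort, path) {
  cohort <- as_cohort_table(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a curated gene list
#'
#' Plain text, one gene symbol per line; blank lines and `#` comments are
#' ignored; duplicates are removed keeping first occurrence.
#'
#' @param path Path to a text file.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  x <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0L) stop("empty gene list: ", path)
  unique(x)
}
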