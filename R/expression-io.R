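#' Expression matrix container
#'
#' A samples-by-features matrix of nonnegative expression values (read counts
#' or transformed expression) with a class label per feature. Rows are
#' samples, columns are features; both must carry unique identifiers and the
#' body must be complete — missing entries are an error, never imputed.
#'
#' @param values Numeric matrix, rows = samples, columns = features, with
#'   dimnames giving sample and feature identifiers.
#' @param feature_class Character vector, one of `"miRNA"` or `"mRNA"` per
#'   feature; either length 1 (recycled) or one entry per column of `values`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `sample_ids`, `feature_ids`, `feature_class`.
#' @export
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("s", 1:3), paste0("f", 1:2)))
#' expression_matrix(m, "miRNA")
expression_matrix <- function(values, feature_class) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("expression matrix is empty", call. = FALSE)
  }
  sample_ids <- rownames(values)
  feature_ids <- colnames(values)
  if (is.null(sample_ids) || is.null(feature_ids)) {
    stop("`values` must have sample (row) and feature (column) names", call. = FALSE)
  }
  check_unique(sample_ids, "sample")
  check_unique(feature_ids, "feature")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at sample '%s', feature '%s'",
                 sample_ids[bad[1]], feature_ids[bad[2]]), call. = FALSE)
  }
  if (length(feature_class) == 1L) {
    feature_class <- rep(feature_class, length(feature_ids))
  }
  if (length(feature_class) != length(feature_ids)) {
    stop("`feature_class` must have one entry per feature", call. = FALSE)
  }
  if (!all(feature_class %in% c("miRNA", "mRNA"))) {
    stop("feature classes must be 'miRNA' or 'mRNA'", call. = FALSE)
  }
  structure(
    list(values = values,
         sample_ids = sample_ids,
         feature_ids = feature_ids,
         feature_class = setNames(feature_class, feature_ids)),
    class = "expr_matrix"
  )
}

check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate %s IDs: %s", what, paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  invisible(ids)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cls <- table(x$feature_class)
  cat(sprintf("<expr_matrix> %d samples x %d features (%s)\n",
              length(x$sample_ids), length(x$feature_ids),
              paste(sprintf("%s %s", cls, names(cls)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @describeIn expression_matrix Long-format view: one row per
#'   (sample, feature) cell with columns `sample_id`, `feature_id`, `class`,
#'   `value`.
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  tibble(
    sample_id = rep(x$sample_ids, times = length(x$feature_ids)),
    feature_id = rep(x$feature_ids, each = length(x$sample_ids)),
    class = rep(unname(x$feature_class), each = length(x$sample_ids)),
    value = as.vector(x$values)
  )
}

#' Read an expression matrix from TSV
#'
#' The file dialect is a single consolidated tab-separated table: first row =
#' feature IDs, first column = sample IDs, numeric body. Orientation is
#' normalized to samples x features.
#'
#' @param path Path to a TSV file.
#' @param class_label Feature class for every column, `"miRNA"` or `"mRNA"`.
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(path, class_label) {
  raw <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                    check.names = FALSE, colClasses = "character",
                    comment.char = "", quote = "")
  if (nrow(raw) == 0L || ncol(raw) == 0L) {
    stop(sprintf("empty expression matrix in '%s'", path), call. = FALSE)
  }
  vals <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L)
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in '%s'",
                 raw[bad[1], bad[2]], rownames(raw)[bad[1]],
                 colnames(raw)[bad[2]], path), call. = FALSE)
  }
  dimnames(vals) <- list(rownames(raw), colnames(raw))
  expression_matrix(vals, class_label)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: round-tripping preserves values and IDs.
#'
#' @param expr An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  df <- data.frame(sample_id = expr$sample_ids,
                   format_num(expr$values),
                   check.names = FALSE)
  colnames(df) <- c("sample_id", expr$feature_ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Deterministic numeric formatting shared by all writers (byte-stable reruns,
# 17 significant digits so doubles round-trip exactly).
format_num <- function(x) {
  out <- formatC(x, format = "g", digits = 17)
  out <- gsub(" ", "", out, fixed = TRUE)
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' Read a clinical table
#'
#' Expects a TSV with a `sample_id` column and any of the endpoint columns
#' `survival_days` (nonnegative integer), `er_status`
#' (`positive`/`negative`), and `stage` (`I`-`IV`). Missing endpoints are
#' encoded as `NA` (empty cells or the literal `NA`); unused columns are
#' ignored.
#'
#' @param path Path to a TSV file.
#' @return A `clinical_table`: a tibble with columns `sample_id`,
#'   `survival_days`, `er_status`, `stage`.
#' @export
read_clinical <- function(path) {
  raw <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", comment.char = "", quote = "",
                    na.strings = c("NA", ""))
  if (!"sample_id" %in% colnames(raw)) {
    stop("clinical table must have a 'sample_id' column", call. = FALSE)
  }
  clinical_table(
    sample_id = raw$sample_id,
    survival_days = if ("survival_days" %in% colnames(raw))
      as.numeric(raw$survival_days) else NA_real_,
    er_status = if ("er_status" %in% colnames(raw)) raw$er_status else NA_character_,
    stage = if ("stage" %in% colnames(raw)) raw$stage else NA_character_
  )
}

#' Clinical table constructor
#'
#' @param sample_id Unique sample identifiers.
#' @param survival_days Nonnegative survival time in days, or `NA`.
#' @param er_status `"positive"`, `"negative"`, or `NA`.
#' @param stage `"I"`, `"II"`, `"III"`, `"IV"`, or `NA`.
#' @return A tibble of class `clinical_table`.
#' @export
clinical_table <- function(sample_id, survival_days = NA_real_,
                           er_status = NA_character_, stage = NA_character_) {
  check_unique(sample_id, "sample")
  tab <- tibble(sample_id = as.character(sample_id),
                survival_days = as.numeric(survival_days),
                er_status = as.character(er_status),
                stage = as.character(stage))
  if (any(!is.na(tab$survival_days) & tab$survival_days < 0)) {
    stop("survival_days must be nonnegative", call. = FALSE)
  }
  bad_er <- setdiff(unique(tab$er_status), c("positive", "negative", NA))
  if (length(bad_er)) {
    stop(sprintf("invalid er_status value(s): %s", paste(bad_er, collapse = ", ")),
         call. = FALSE)
  }
  bad_stage <- setdiff(unique(tab$stage), c("I", "II", "III", "IV", NA))
  if (length(bad_stage)) {
    stop(sprintf("invalid stage value(s): %s", paste(bad_stage, collapse = ", ")),
         call. = FALSE)
  }
  class(tab) <- c("clinical_table", class(tab))
  tab
}

#' Write a clinical table to TSV
#'
#' @param clinical A `clinical_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  df <- as.data.frame(clinical)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Integrate miRNA and mRNA expression into one joint matrix
#'
#' Column-binds the two matrices over a shared sample set, miRNA block first,
#' preserving feature class labels. The second matrix may list the samples in
#' a different order; it is aligned by ID.
#'
#' @param mirna,mrna `expr_matrix` objects over identical sample sets with
#'   disjoint feature IDs.
#' @return The joint `expr_matrix` Z with `ncol(mirna) + ncol(mrna)` features.
#' @export
integrate_expression <- function(mirna, mrna) {
  stopifnot(inherits(mirna, "expr_matrix"), inherits(mrna, "expr_matrix"))
  only_a <- setdiff(mirna$sample_ids, mrna$sample_ids)
  only_b <- setdiff(mrna$sample_ids, mirna$sample_ids)
  if (length(only_a) || length(only_b)) {
    stop(sprintf(
      "sample sets differ: only in first [%s]; only in second [%s]",
      paste(only_a, collapse = ", "), paste(only_b, collapse = ", ")),
      call. = FALSE)
  }
  clash <- intersect(mirna$feature_ids, mrna$feature_ids)
  if (length(clash)) {
    stop(sprintf("feature ID collision: %s", paste(clash, collapse = ", ")),
         call. = FALSE)
  }
  vals <- cbind(mirna$values, mrna$values[mirna$sample_ids, , drop = FALSE])
  expression_matrix(vals, c(unname(mirna$feature_class),
                            unname(mrna$feature_class)))
}

#' Subset an expression matrix by feature ID
#'
#' @param expr An `expr_matrix`.
#' @param feature_ids Features to keep (order preserved as given).
#' @return An `expr_matrix` with the selected features.
#' @export
select_features <- function(expr, feature_ids) {
  stopifnot(inherits(expr, "expr_matrix"))
  missing <- setdiff(feature_ids, expr$feature_ids)
  if (length(missing)) {
    stop(sprintf("unknown feature(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  expression_matrix(expr$values[, feature_ids, drop = FALSE],
                    unname(expr$feature_class[feature_ids]))
}
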