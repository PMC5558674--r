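#' Assign samples to two comparison groups from a clinical endpoint
#'
#' Implements the three endpoint rules used to dichotomize each cohort:
#' \describe{
#'   \item{`survival_1yr`}{group A (high-risk) = survival \eqn{\le} 365 days;
#'     group B (low-risk) = survival > 365 days. Exactly 365 days counts as
#'     high-risk. Recorded survival days are used as-is; censoring is not
#'     modeled (a warning notes this).}
#'   \item{`er_status`}{group A = ER-negative, group B = ER-positive.}
#'   \item{`stage`}{group A (high-risk) = pathological stages III/IV,
#'     group B (low-risk) = stages I/II.}
#'   \item{`explicit`}{groups supplied directly via `group_a`/`group_b`.}
#' }
#' Samples whose endpoint is absent are excluded and reported in the
#' `excluded` field.
#'
#' @param clinical A [clinical_table()] (not needed for `rule = "explicit"`
#'   if both groups are given).
#' @param rule One of `"survival_1yr"`, `"er_status"`, `"stage"`,
#'   `"explicit"`.
#' @param group_a,group_b Sample IDs for `rule = "explicit"`.
#' @return A `group_assignment`: list with `group_a`, `group_b`, `excluded`,
#'   `rule`.
#' @export
assign_groups <- function(clinical, rule = c("survival_1yr", "er_status",
                                             "stage", "explicit"),
                          group_a = NULL, group_b = NULL) {
  rule <- match.arg(rule)
  if (rule == "explicit") {
    if (is.null(group_a) || is.null(group_b)) {
      stop("rule 'explicit' requires `group_a` and `group_b`", call. = FALSE)
    }
    if (length(intersect(group_a, group_b))) {
      stop("groups must be disjoint", call. = FALSE)
    }
    if (!missing(clinical) && !is.null(clinical)) {
      unknown <- setdiff(c(group_a, group_b), clinical$sample_id)
      if (length(unknown)) {
        stop(sprintf("sample(s) not in clinical table: %s",
                     paste(unknown, collapse = ", ")), call. = FALSE)
      }
    }
    return(new_group_assignment(group_a, group_b, character(), rule))
  }

  stopifnot(inherits(clinical, "clinical_table"))
  ids <- clinical$sample_id
  if (rule == "survival_1yr") {
    v <- clinical$survival_days
    if (all(is.na(v))) stop("no survival_days data for rule 'survival_1yr'",
                            call. = FALSE)
    warning("survival_days used as recorded; censoring is ignored",
            call. = FALSE)
    a <- ids[!is.na(v) & v <= 365]
    b <- ids[!is.na(v) & v > 365]
    excl <- ids[is.na(v)]
  } else if (rule == "er_status") {
    v <- clinical$er_status
    if (all(is.na(v))) stop("no er_status data for rule 'er_status'",
                            call. = FALSE)
    a <- ids[!is.na(v) & v == "negative"]
    b <- ids[!is.na(v) & v == "positive"]
    excl <- ids[is.na(v)]
  } else {
    v <- clinical$stage
    if (all(is.na(v))) stop("no stage data for rule 'stage'", call. = FALSE)
    a <- ids[!is.na(v) & v %in% c("III", "IV")]
    b <- ids[!is.na(v) & v %in% c("I", "II")]
    excl <- ids[is.na(v)]
  }
  new_group_assignment(a, b, excl, rule)
}

new_group_assignment <- function(group_a, group_b, excluded, rule) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop(sprintf("rule '%s' produced an empty group (A: %d, B: %d samples)",
                 rule, length(group_a), length(group_b)), call. = FALSE)
  }
  structure(list(group_a = as.character(group_a),
                 group_b = as.character(group_b),
                 excluded = as.character(excluded),
                 rule = rule),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("<group_assignment> rule = %s: %d vs %d samples (%d excluded)\n",
              x$rule, length(x$group_a), length(x$group_b), length(x$excluded)))
  invisible(x)
}

#' Student's (pooled-variance) two-sample t-test P value
#'
#' Two-sided pooled-variance t-test. When both groups are constant the test
#' statistic is undefined; the P value is then 1 if the group means are equal
#' (no evidence of difference) and 0 otherwise (the zero-variance limit).
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return The two-sided P value.
#' @export
de_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  pooled_var <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
    (length(x) + length(y) - 2)
  if (pooled_var == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = TRUE)$p.value
}

#' Fold change between two groups
#'
#' Ratio of group means, group A over group B. Undefined (`NA`) when the
#' group B mean is zero.
#'
#' @param x Group A values (numerator), nonnegative.
#' @param y Group B values (denominator), nonnegative.
#' @return `mean(x) / mean(y)`, or `NA` if `mean(y) == 0`.
#' @export
fold_change <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("fold change needs nonempty groups", call. = FALSE)
  }
  if (any(x < 0) || any(y < 0)) {
    stop("fold change requires nonnegative values", call. = FALSE)
  }
  my <- mean(y)
  if (my == 0) return(NA_real_)
  mean(x) / my
}

#' Identify differentially expressed features
#'
#' The two-stage filter: features are kept when the Student's t-test P value
#' is below `p_threshold`, and of those, when the fold change (group A mean
#' over group B mean) is strictly above `upper_fc` or strictly below
#' `lower_fc`. Both bounds are applied as printed (1.5 and 0.667), not as
#' exact reciprocals. Features whose fold change is undefined (group B mean
#' zero) never pass. An optional `log2(x + 1)` pre-transform is available but
#' off by default: the test and ratio are computed on the values as loaded.
#'
#' @param expr An [expression_matrix()].
#' @param groups A [assign_groups()] result; all listed samples must be
#'   present in `expr`.
#' @param p_threshold P value cutoff (default 0.05).
#' @param upper_fc,lower_fc Fold-change gates (defaults 1.5 and 0.667).
#' @param log2p1 Apply `log2(x + 1)` before testing (default `FALSE`).
#' @return A tibble of class `de_results`, one row per feature in input
#'   order: `feature_id`, `class`, `p_value`, `fold_change`, `passes`.
#' @export
select_differential <- function(expr, groups, p_threshold = 0.05,
                                upper_fc = 1.5, lower_fc = 0.667,
                                log2p1 = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"),
            inherits(groups, "group_assignment"))
  missing <- setdiff(c(groups$group_a, groups$group_b), expr$sample_ids)
  if (length(missing)) {
    stop(sprintf("group sample(s) missing from expression matrix: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  vals <- expr$values
  if (log2p1) vals <- log2(vals + 1)
  xa <- vals[groups$group_a, , drop = FALSE]
  xb <- vals[groups$group_b, , drop = FALSE]

  res <- purrr::map(seq_along(expr$feature_ids), function(j) {
    p <- tryCatch(de_t_test(xa[, j], xb[, j]), error = function(e) NA_real_)
    fc <- tryCatch(fold_change(xa[, j], xb[, j]), error = function(e) NA_real_)
    list(p = p, fc = fc)
  })
  p_value <- purrr::map_dbl(res, "p")
  fc <- purrr::map_dbl(res, "fc")
  passes <- !is.na(p_value) & p_value < p_threshold &
    !is.na(fc) & (fc > upper_fc | fc < lower_fc)

  out <- tibble(
    feature_id = expr$feature_ids,
    class = unname(expr$feature_class),
    p_value = p_value,
    fold_change = fc,
    passes = passes
  )
  attr(out, "thresholds") <- list(p_threshold = p_threshold,
                                  upper_fc = upper_fc, lower_fc = lower_fc)
  class(out) <- c("de_results", class(out))
  out
}

#' Volcano-style view of a differential expression table
#'
#' @param object A `de_results` tibble from [select_differential()].
#' @param ... Unused.
#' @return A ggplot: log2 fold change vs -log10 P, passing features
#'   highlighted.
#' @export
autoplot.de_results <- function(object, ...) {
  th <- attr(object, "thresholds")
  df <- dplyr::filter(object, !is.na(.data$fold_change), .data$fold_change > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$fold_change),
                                   y = -log10(.data$p_value),
                                   colour = .data$passes)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = log2(c(th$lower_fc, th$upper_fc)),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(th$p_threshold),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (group A / group B)",
                  y = "-log10 P (Student's t)",
                  colour = "differential")
}
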