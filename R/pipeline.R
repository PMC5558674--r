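#' Default pipeline configuration
#'
#' The full parameter set of an end-to-end run, with the study's defaults:
#' P < 0.05 and fold change outside (0.667, 1.5) for the differential filter,
#' penalty rho = 2.0 for the graphical lasso, top 20 hub miRNAs, and a
#' minimum of 3 miRNAs for the multi-target report.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    expr_mirna = NULL,      # path to miRNA expression TSV (or expr_matrix)
    expr_mrna = NULL,       # path to mRNA expression TSV (or expr_matrix)
    clinical = NULL,        # path to clinical TSV (or clinical_table)
    rule = "survival_1yr",
    p_threshold = 0.05,
    upper_fc = 1.5,
    lower_fc = 0.667,
    de_log2p1 = FALSE,
    transform = "log2p1",
    scale = "correlation",
    center_groups = TRUE,
    rho = 2.0,
    tol = 1e-4,
    max_iter = 100L,
    edge_eps = 1e-8,
    top_k = 20L,
    min_mirnas = 3L,
    out_dir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$p_threshold > 0, cfg$p_threshold <= 1,
            cfg$upper_fc > 0, cfg$lower_fc > 0, cfg$lower_fc < cfg$upper_fc,
            cfg$rho >= 0, cfg$tol > 0, cfg$max_iter >= 1,
            cfg$edge_eps >= 0, cfg$top_k >= 1, cfg$min_mirnas >= 1)
  if (!cfg$rule %in% c("survival_1yr", "er_status", "stage", "explicit")) {
    stop(sprintf("unknown grouping rule '%s'", cfg$rule), call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Read a flat key-value pipeline configuration file
#'
#' One `key: value` pair per line (`#` comments and blank lines ignored);
#' keys and defaults as in [run_config()].
#'
#' @param path Path to the config file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  parsed <- lapply(vals, function(v) {
    if (v %in% c("true", "TRUE")) return(TRUE)
    if (v %in% c("false", "FALSE")) return(FALSE)
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(parsed) <- keys
  do.call(run_config, parsed)
}

#' Run the full interaction-network pipeline
#'
#' Executes the study's stages in order: group assignment from the clinical
#' endpoint; differential-expression filtering of miRNAs and mRNAs (same
#' groups, same thresholds); integration of the passing features into the
#' joint matrix Z; empirical covariance; graphical lasso; network
#' construction; bipartite view; hub ranking; multi-target report. Per-stage
#' outputs are written under `out_dir` with fixed names
#' (`de_mirna.tsv`, `de_mrna.tsv`, `theta.tsv`, `edges.tsv`,
#' `edges_bipartite.tsv`, `hubs.tsv`, `multi_targets.tsv`, `manifest.json`).
#' Stage outputs are byte-identical across reruns with identical config and
#' inputs; the manifest additionally records wall-clock times.
#'
#' @param config A `run_config`, a named list of overrides, or a path to a
#'   flat config file. Input entries (`expr_mirna`, `expr_mrna`, `clinical`)
#'   may be file paths or in-memory objects.
#' @param quiet Suppress stage progress messages (default `FALSE`; messages
#'   go to stderr).
#' @return The run manifest, invisibly: a list with the config, per-stage
#'   feature counts, convergence flag, package version, and timings. Also
#'   written as `manifest.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  } else if (!inherits(config, "run_config")) {
    config <- do.call(run_config, config)
  }
  cfg <- config
  if (is.null(cfg$out_dir)) stop("config needs an out_dir", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  mirna <- clock("read", {
    m1 <- if (inherits(cfg$expr_mirna, "expr_matrix")) cfg$expr_mirna
          else read_expression(cfg$expr_mirna, "miRNA")
    m1
  })
  mrna <- if (inherits(cfg$expr_mrna, "expr_matrix")) cfg$expr_mrna
          else read_expression(cfg$expr_mrna, "mRNA")
  clinical <- if (inherits(cfg$clinical, "clinical_table")) cfg$clinical
              else read_clinical(cfg$clinical)
  say("read: %d miRNAs, %d mRNAs, %d clinical samples",
      ncol(mirna$values), ncol(mrna$values), nrow(clinical))

  groups <- clock("groups", assign_groups(clinical, cfg$rule))
  say("groups (%s): %d vs %d samples, %d excluded", cfg$rule,
      length(groups$group_a), length(groups$group_b), length(groups$excluded))

  de_mirna <- clock("de_mirna",
    select_differential(mirna, groups, cfg$p_threshold, cfg$upper_fc,
                        cfg$lower_fc, log2p1 = cfg$de_log2p1))
  de_mrna <- clock("de_mrna",
    select_differential(mrna, groups, cfg$p_threshold, cfg$upper_fc,
                        cfg$lower_fc, log2p1 = cfg$de_log2p1))
  keep_mirna <- de_mirna$feature_id[de_mirna$passes]
  keep_mrna <- de_mrna$feature_id[de_mrna$passes]
  say("differential: %d/%d miRNAs, %d/%d mRNAs pass",
      length(keep_mirna), ncol(mirna$values),
      length(keep_mrna), ncol(mrna$values))
  write_de(de_mirna, file.path(cfg$out_dir, "de_mirna.tsv"))
  write_de(de_mrna, file.path(cfg$out_dir, "de_mrna.tsv"))
  if (length(keep_mirna) + length(keep_mrna) == 0L) {
    stop("no differentially expressed features; consider relaxing p_threshold or the fold-change gates",
         call. = FALSE)
  }
  if (length(keep_mirna) == 0L || length(keep_mrna) == 0L) {
    warning("one feature class has no differential features; the bipartite network will be empty",
            call. = FALSE)
  }

  z <- clock("integrate", integrate_expression(
    select_features(mirna, keep_mirna), select_features(mrna, keep_mrna)))
  cov_in <- clock("covariance",
    empirical_covariance(z, transform = cfg$transform, scale = cfg$scale,
                         groups = if (isTRUE(cfg$center_groups)) groups))
  fit <- clock("glasso", graphical_lasso(cov_in, rho = cfg$rho, tol = cfg$tol,
                                         max_iter = cfg$max_iter))
  if (!fit$converged) {
    warning(sprintf("graphical lasso did not converge in %d sweeps (KKT residual %.3e); results flagged in the manifest",
                    fit$iterations, fit$kkt_residual), call. = FALSE)
  }
  say("glasso: rho = %g, %d sweeps, %s", cfg$rho, fit$iterations,
      if (fit$converged) "converged" else "NOT converged")
  write_matrix_tsv(fit$theta, file.path(cfg$out_dir, "theta.tsv"))

  net <- clock("network", build_network(fit, edge_eps = cfg$edge_eps,
                                        force = TRUE))
  bip <- bipartite_view(net)
  hubs <- rank_hubs(bip, top_k = cfg$top_k)
  targets <- multi_target_genes(bip, min_mirnas = cfg$min_mirnas)
  say("network: %d edges (%d bipartite), %d ranked hubs, %d multi-target mRNAs",
      nrow(net$edges), nrow(bip$edges), nrow(hubs), nrow(targets))

  write_edge_list(net, file.path(cfg$out_dir, "edges.tsv"))
  write_edge_list(bip, file.path(cfg$out_dir, "edges_bipartite.tsv"))
  write.table(as.data.frame(hubs), file.path(cfg$out_dir, "hubs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tdf <- data.frame(
    mrna = targets$mrna,
    n_mirnas = targets$n_mirnas,
    mirnas = vapply(targets$mirnas, paste, "", collapse = ","))
  write.table(tdf, file.path(cfg$out_dir, "multi_targets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    config = unclass(cfg[!vapply(cfg, is.object, TRUE)]),
    version = as.character(packageVersion("mirlasso")),
    counts = list(
      mirna_in = ncol(mirna$values), mrna_in = ncol(mrna$values),
      samples_group_a = length(groups$group_a),
      samples_group_b = length(groups$group_b),
      samples_excluded = length(groups$excluded),
      de_mirna = length(keep_mirna), de_mrna = length(keep_mrna),
      glasso_features = length(cov_in$feature_ids),
      constant_dropped = length(cov_in$dropped),
      edges = nrow(net$edges), edges_bipartite = nrow(bip$edges),
      hubs_ranked = nrow(hubs), multi_target_mrnas = nrow(targets)
    ),
    glasso = list(rho = cfg$rho, iterations = fit$iterations,
                  converged = fit$converged,
                  kkt_residual = fit$kkt_residual,
                  objective = fit$objective),
    timings_sec = timings
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

write_de <- function(de, path) {
  df <- as.data.frame(de)
  df$p_value <- format_num(df$p_value)
  df$fold_change <- format_num(df$fold_change)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

write_matrix_tsv <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), format_num(mat),
                   check.names = FALSE)
  colnames(df) <- c("feature_id", colnames(mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
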