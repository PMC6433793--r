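# End-to-end orchestration: simulate (or load) a cohort, condition the time
# series, build thresholded networks over the sparsity grid, integrate metric
# curves, and run the covariate-adjusted permutation comparison and clinical
# correlations. All randomness flows from the single config seed through
# named substreams so repeated runs are byte-identical.

#' Pipeline configuration
#'
#' @param grid \code{sparsity_grid} (default 0.10..0.34 step 0.01).
#' @param band band-pass edges in Hz (default c(0.01, 0.08)).
#' @param n_discard initial volumes to drop (default 10).
#' @param n_perm permutations for group tests (default 10000).
#' @param n_null null networks per sparsity (default 100).
#' @param n_swaps_per_edge rewiring effort per null (default 10).
#' @param fdr_q FDR level (default 0.05).
#' @param covariate_cols covariates removed before group tests
#'   (default age, sex).
#' @param seed master seed (default 1).
#' @return List of class \code{run_config}.
#' @export
run_config <- function(grid = sparsity_grid(), band = c(0.01, 0.08),
                       n_discard = 10L, n_perm = 10000L, n_null = 100L,
                       n_swaps_per_edge = 10L, fdr_q = 0.05,
                       covariate_cols = c("age", "sex"), seed = 1L) {
  stopifnot(inherits(grid, "sparsity_grid"))
  structure(list(grid = grid, band = band, n_discard = as.integer(n_discard),
                 n_perm = as.integer(n_perm), n_null = as.integer(n_null),
                 n_swaps_per_edge = as.integer(n_swaps_per_edge),
                 fdr_q = fdr_q, covariate_cols = covariate_cols,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize / deserialize a run configuration as JSON
#'
#' @param config \code{run_config}.
#' @param path file path.
#' @export
write_config_json <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$grid <- list(s_min = config$grid$s_min, s_max = config$grid$s_max,
                 delta_s = config$grid$delta_s)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- x$grid
  run_config(grid = sparsity_grid(g$s_min, g$s_max, g$delta_s),
             band = x$band, n_discard = x$n_discard, n_perm = x$n_perm,
             n_null = x$n_null, n_swaps_per_edge = x$n_swaps_per_edge,
             fdr_q = x$fdr_q, covariate_cols = x$covariate_cols,
             seed = x$seed)
}

# independent substream seeds derived from the master seed
.substream_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(2^31 - 2, 3L)
  list(simulation = s[1L], metrics = s[2L], permutation = s[3L])
}

#' Run the full analysis on in-memory inputs
#'
#' @param timeseries list of \code{roi_timeseries}, one per subject (already
#'   extracted ROI signals; raw scanner volumes are upstream of this
#'   package).
#' @param cohort cohort data.frame (subject_id, group, covariates,
#'   clinical variables).
#' @param config \code{run_config}.
#' @param prep apply the conditioning pipeline (discard/detrend/band-pass)
#'   to each subject first (default TRUE; set FALSE when the series are
#'   already conditioned, e.g. straight out of \code{\link{make_cohort}}).
#' @param include_nodal compute nodal metrics and their tests (default TRUE).
#' @param clinical_cols clinical variables for the correlation stage
#'   (default: the numeric cohort columns that are not covariates).
#' @return List of class \code{pipeline_result}: \code{metrics} (long
#'   per-sparsity table), \code{aucs}, \code{comparison},
#'   \code{correlations}, \code{demographics}, \code{config}.
#' @export
run_pipeline <- function(timeseries, cohort, config = run_config(),
                         prep = TRUE, include_nodal = TRUE,
                         clinical_cols = NULL) {
  stopifnot(inherits(config, "run_config"))
  ids <- vapply(timeseries, function(t) t$subject_id, character(1))
  if (!setequal(ids, cohort$subject_id))
    stop("time-series subjects and cohort table disagree")
  timeseries <- timeseries[match(cohort$subject_id, ids)]
  seeds <- .substream_seeds(config$seed)

  if (prep) {
    timeseries <- lapply(timeseries, prep_timeseries,
                         n_discard = config$n_discard,
                         low_hz = config$band[1], high_hz = config$band[2])
  }

  set.seed(seeds$metrics)
  curves <- vector("list", length(timeseries))
  for (i in seq_along(timeseries)) {
    cm <- correlation_matrix(timeseries[[i]])
    curves[[i]] <- metric_curves(cm, grid = config$grid,
                                 n_null = config$n_null,
                                 n_swaps_per_edge = config$n_swaps_per_edge,
                                 include_nodal = include_nodal,
                                 subject_id = cohort$subject_id[i])
  }

  long <- do.call(rbind, lapply(curves, function(cv) {
    g <- utils::stack(cv$global, select = -sparsity)
    data.frame(subject_id = cv$subject_id,
               sparsity = rep(cv$global$sparsity, ncol(cv$global) - 1L),
               metric = as.character(g$ind), node = NA_character_,
               value = g$values, stringsAsFactors = FALSE)
  }))
  aucs <- do.call(rbind, lapply(curves, auc_table))

  comparison <- compare_groups(aucs, cohort,
                               covariate_cols = config$covariate_cols,
                               n_perm = config$n_perm, fdr_q = config$fdr_q,
                               seed = seeds$permutation)
  if (is.null(clinical_cols)) {
    num <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
    clinical_cols <- setdiff(num, c(config$covariate_cols, "sex"))
  }
  correlations <- clinical_correlations(aucs, cohort,
                                        clinical_cols = clinical_cols,
                                        covariate_cols = config$covariate_cols)
  structure(list(metrics = long, aucs = aucs, comparison = comparison,
                 correlations = correlations,
                 demographics = demographics_compare(cohort),
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  subjects:", length(unique(x$aucs$subject_id)),
      "| sparsity levels:", length(x$config$grid$points),
      "| permutations:", x$config$n_perm, "\n")
  sig <- x$comparison[x$comparison$significant, , drop = FALSE]
  cat("  significant after FDR:", nrow(sig), "of", nrow(x$comparison),
      "tests\n")
  invisible(x)
}

#' Run the pipeline from files and write result tables
#'
#' Reads per-subject time-series TSVs and the cohort CSV, runs
#' \code{\link{run_pipeline}}, and writes \code{metrics.tsv},
#' \code{aucs.tsv}, \code{comparison.tsv}, \code{correlations.tsv},
#' \code{demographics.tsv} and the resolved \code{config.json} to
#' \code{out_dir}.
#'
#' @param input_dir directory holding \code{cohort.csv} and one
#'   \code{<subject_id>.tsv} per subject.
#' @param out_dir output directory (created if missing).
#' @param config \code{run_config}.
#' @param tr_seconds sampling interval of the stored series (default 2).
#' @param ... forwarded to \code{\link{run_pipeline}}.
#' @return The \code{pipeline_result}, invisibly.
#' @export
run_pipeline_files <- function(input_dir, out_dir, config = run_config(),
                               tr_seconds = 2, ...) {
  cohort <- read_cohort_csv(file.path(input_dir, "cohort.csv"))
  timeseries <- lapply(cohort$subject_id, function(id) {
    read_timeseries_tsv(file.path(input_dir, paste0(id, ".tsv")),
                        tr_seconds = tr_seconds, subject_id = id)
  })
  res <- run_pipeline(timeseries, cohort, config = config, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(res$metrics, "metrics.tsv")
  wt(res$aucs, "aucs.tsv")
  wt(res$comparison, "comparison.tsv")
  if (!is.null(res$correlations)) wt(res$correlations, "correlations.tsv")
  wt(res$demographics, "demographics.tsv")
  write_config_json(config, file.path(out_dir, "config.json"))
  invisible(res)
}
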