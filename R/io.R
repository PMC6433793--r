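# Plain-text interchange: per-subject time-series TSVs (T rows x N columns,
# header row of ROI labels), square matrix TSVs, and the cohort CSV. Every
# writer's output round-trips through the matching reader.

.check_numeric_table <- function(df, path) {
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad) > 0L)
    stop("non-numeric cells in ", path, " (column ",
         paste(names(df)[bad], collapse = ", "), ")")
}

#' Write / read an ROI time-series TSV
#'
#' @param ts \code{roi_timeseries}.
#' @param path file path.
#' @return \code{write_timeseries_tsv}: invisibly, the path.
#' @export
write_timeseries_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  utils::write.table(ts$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @param tr_seconds,subject_id metadata not stored in the TSV itself.
#' @return \code{read_timeseries_tsv}: an \code{roi_timeseries}.
#' @export
read_timeseries_tsv <- function(path, tr_seconds = 2, subject_id = NULL) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE)
  .check_numeric_table(df, path)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  roi_timeseries(as.matrix(df), tr_seconds = tr_seconds,
                 subject_id = subject_id, roi_labels = names(df))
}

#' Write / read a square labelled matrix TSV
#'
#' Used for connectivity matrices and adjacency matrices.
#'
#' @param m numeric matrix with dimnames.
#' @param path file path.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(as.matrix(m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE)
  .check_numeric_table(df, path)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square")
  rownames(m) <- colnames(m)
  m
}

#' Write / read the cohort table CSV
#'
#' @param cohort data.frame with subject_id, group, covariates, clinical
#'   variables.
#' @param path file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("cohort table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write a whole simulated cohort to a directory
#'
#' One TSV per subject (\code{<subject_id>.tsv}), \code{cohort.csv}, and the
#' ground-truth adjacency \code{ground_truth.tsv}.
#'
#' @param cohort_sim result of \code{\link{make_cohort}}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_cohort_dir <- function(cohort_sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ts in cohort_sim$timeseries)
    write_timeseries_tsv(ts, file.path(dir, paste0(ts$subject_id, ".tsv")))
  write_cohort_csv(cohort_sim$cohort, file.path(dir, "cohort.csv"))
  gt <- cohort_sim$ground_truth$adjacency
  labels <- cohort_sim$timeseries[[1L]]$roi_labels
  dimnames(gt) <- list(labels, labels)
  write_matrix_tsv(gt, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
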