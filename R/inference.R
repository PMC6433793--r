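# Covariate-adjusted nonparametric group comparison: OLS residualization of
# AUC statistics on nuisance covariates, a label-permutation test on the
# difference of group means, Benjamini-Hochberg FDR across nodes, partial
# correlations with clinical variables, and Table-1-style demographic tests.

#' Residualize values on covariates by ordinary least squares
#'
#' Fits \code{values ~ intercept + covariates} and returns the residuals, so
#' downstream group tests are not driven by age, sex, or other nuisance
#' variables. Collinear covariates trigger a pseudo-inverse fit with a
#' warning.
#'
#' @param values numeric vector (or matrix, residualized column-wise).
#' @param covariates numeric matrix/data.frame with one row per subject, or
#'   NULL for intercept-only (demeaning).
#' @return Residuals with the same shape as \code{values}.
#' @export
residualize <- function(values, covariates = NULL) {
  v <- as.matrix(values)
  n <- nrow(v)
  X <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != n) stop("covariates rows must match values length")
    X <- cbind(X, covariates)
  }
  if (ncol(X) >= n) stop("more covariates than subjects")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("collinear covariates; using pseudo-inverse projection")
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
    U <- sv$u[, pos, drop = FALSE]
    res <- v - U %*% (t(U) %*% v)
  } else {
    res <- qr.resid(qx, v)
  }
  if (is.vector(values)) as.numeric(res) else res
}

#' Permutation test for a difference in group means
#'
#' Statistic: mean(second group level) - mean(first group level) (with
#' levels sorted, so \code{patient - control} for those labels).
#' Permutations reassign the group labels without replacement, preserving
#' group sizes; the two-tailed p-value uses the add-one correction
#' \code{p = (#(|null| >= |obs|) + 1) / (n_perm + 1)}.
#'
#' \code{values} may be a matrix (subjects x variables); the same label
#' permutations are shared across columns, as required for a coherent FDR
#' family.
#'
#' @param values numeric vector or subjects-x-m matrix (typically
#'   residualized AUCs).
#' @param groups binary labels, one per subject.
#' @param n_perm number of permutations (default 10000; < 100 warns).
#' @param seed optional RNG seed.
#' @param exhaustive enumerate every distinct label assignment instead of
#'   sampling; the p-value is then the exact fraction
#'   \code{#(|null| >= |obs|) / #assignments} (the identity assignment is
#'   part of the enumeration, so p > 0). Feasible for small cohorts.
#' @return For a vector: list of class \code{permutation_result} with
#'   \code{observed_diff}, \code{null_diffs}, \code{p_value}. For a matrix:
#'   list with vectors \code{observed_diff} and \code{p_value} (one per
#'   column) and matrix \code{null_diffs}.
#' @export
permutation_test <- function(values, groups, n_perm = 10000L, seed = NULL,
                             exhaustive = FALSE) {
  v <- as.matrix(values)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly 2 levels")
  if (any(table(groups) < 2L)) stop("both groups need at least 2 subjects")
  if (nrow(v) != length(groups)) stop("values and groups length mismatch")
  if (!exhaustive && n_perm < 100L)
    warning("n_perm < 100 gives a very coarse p-value")
  if (!is.null(seed)) set.seed(seed)
  g2 <- groups == levels(groups)[2L]
  n2 <- sum(g2); n1 <- sum(!g2); n <- n1 + n2
  diff_of <- function(mask) colSums(v[mask, , drop = FALSE]) / n2 -
    colSums(v[!mask, , drop = FALSE]) / n1
  observed <- diff_of(g2)
  if (exhaustive) {
    combs <- utils::combn(n, n2)
    n_perm <- ncol(combs)
    null_diffs <- matrix(NA_real_, n_perm, ncol(v))
    for (b in seq_len(n_perm)) {
      mask <- logical(n)
      mask[combs[, b]] <- TRUE
      null_diffs[b, ] <- diff_of(mask)
    }
    tol <- 1e-12 * (1 + max(abs(null_diffs)))
    p <- colSums(abs(null_diffs) >= matrix(abs(observed) - tol, n_perm,
                                           ncol(v), byrow = TRUE)) / n_perm
  } else {
    null_diffs <- matrix(NA_real_, n_perm, ncol(v))
    for (b in seq_len(n_perm)) {
      mask <- logical(n)
      mask[sample.int(n, n2)] <- TRUE
      null_diffs[b, ] <- diff_of(mask)
    }
    p <- (colSums(abs(null_diffs) >= matrix(abs(observed), n_perm, ncol(v),
                                            byrow = TRUE)) + 1) / (n_perm + 1)
  }
  if (is.vector(values) || ncol(v) == 1L) {
    structure(list(observed_diff = observed[[1L]],
                   null_diffs = null_diffs[, 1L], p_value = p[[1L]],
                   n_perm = n_perm, levels = levels(groups)),
              class = "permutation_result")
  } else {
    list(observed_diff = observed, null_diffs = null_diffs, p_value = p,
         n_perm = n_perm, levels = levels(groups))
  }
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s - %s = %.4g, p = %.4g (%d permutations)\n",
              x$levels[2L], x$levels[1L], x$observed_diff, x$p_value, x$n_perm))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: adjusted p-values are
#' \code{min over j >= rank of (m p_(j) / j)}, capped at 1; the rejection
#' mask marks every hypothesis with adjusted p <= q.
#'
#' @param p_values numeric vector in [0, 1].
#' @param q target FDR level (default 0.05).
#' @return List with \code{p_adjusted} and logical \code{reject}.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  p_adjusted <- numeric(m)
  p_adjusted[o] <- adj_sorted
  list(p_adjusted = p_adjusted, reject = p_adjusted <= q)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation between the OLS residuals of \code{x} and \code{y}
#' after regression on the covariates (plus intercept); the p-value comes
#' from the t distribution with n - K - 2 degrees of freedom. With no
#' covariates this is the plain Pearson correlation test.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data.frame or NULL.
#' @return List with \code{r}, \code{p}, \code{df}.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y length mismatch")
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + 3L) stop("need n > K + 3 subjects")
  rx <- residualize(x, covariates)
  ry <- residualize(y, covariates)
  tol <- 1e-10
  if (stats::sd(rx) <= tol * max(1, stats::sd(as.numeric(x))) ||
      stats::sd(ry) <= tol * max(1, stats::sd(as.numeric(y))))
    stop("zero-variance residual; partial correlation undefined")
  r <- stats::cor(rx, ry)
  df <- n - k - 2L
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, p = p, df = df)
}

#' Demographic and clinical group comparison table
#'
#' Categorical variables are compared with the two-sided exact (Fisher) test
#' on the 2x2 contingency table; continuous variables with pooled-variance
#' two-sample t-tests. Variables observed in only one group yield NA.
#'
#' @param cohort data.frame with a 2-level \code{group} column.
#' @param continuous character vector of continuous variable names (default:
#'   every numeric column except \code{sex}).
#' @param categorical character vector of categorical variable names
#'   (default \code{"sex"} if present).
#' @param chisq_variant for categorical tests: \code{"exact"} (default),
#'   \code{"pearson"} (uncorrected chi-squared) or \code{"yates"}.
#' @return data.frame: variable, mean/sd (or counts) per group, test, p.
#' @export
demographics_compare <- function(cohort, continuous = NULL, categorical = NULL,
                                 chisq_variant = c("exact", "pearson", "yates")) {
  chisq_variant <- match.arg(chisq_variant)
  g <- factor(cohort$group)
  if (nlevels(g) != 2L) stop("cohort must contain exactly 2 groups")
  lv <- levels(g)
  if (is.null(categorical)) categorical <- intersect("sex", names(cohort))
  if (is.null(continuous)) {
    num <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
    continuous <- setdiff(num, categorical)
  }
  rows <- list()
  for (v in categorical) {
    tab <- table(factor(cohort[[v]]), g)
    p <- switch(chisq_variant,
      exact = stats::fisher.test(tab)$p.value,
      pearson = stats::chisq.test(tab, correct = FALSE)$p.value,
      yates = stats::chisq.test(tab, correct = TRUE)$p.value)
    fmt <- function(col) paste(rev(tab[, col]), collapse = "/")
    rows[[v]] <- data.frame(variable = v, group1 = fmt(lv[1]),
                            group2 = fmt(lv[2]),
                            test = chisq_variant, p = p,
                            stringsAsFactors = FALSE)
  }
  for (v in continuous) {
    x1 <- cohort[[v]][g == lv[1]]; x2 <- cohort[[v]][g == lv[2]]
    x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
    ok <- length(x1) >= 2L && length(x2) >= 2L &&
      (stats::sd(x1) > 0 || stats::sd(x2) > 0)
    p <- if (ok) stats::t.test(x1, x2, var.equal = TRUE)$p.value else NA_real_
    fmt <- function(x) if (length(x) < 2L) "-" else
      sprintf("%.2f (+/- %.2f)", mean(x), stats::sd(x))
    rows[[v]] <- data.frame(variable = v, group1 = fmt(x1), group2 = fmt(x2),
                            test = "t", p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[2:3] <- lv
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted permutation comparison of AUC statistics
#'
#' For every metric (and node, for nodal metrics) in a long AUC table:
#' residualize the per-subject AUC on the covariates, run the group
#' permutation test with shared permutations inside each metric family, and
#' apply Benjamini-Hochberg FDR across nodes within each nodal metric family
#' (global metrics are corrected as their own family).
#'
#' @param aucs long data.frame from \code{\link{auc_table}} rows bound over
#'   subjects (columns subject_id, metric, node, auc).
#' @param cohort data.frame with subject_id, group and covariate columns.
#' @param covariate_cols character names of covariate columns
#'   (default \code{c("age", "sex")}).
#' @param n_perm permutations per family (default 10000).
#' @param fdr_q FDR level (default 0.05).
#' @param seed optional RNG seed.
#' @return data.frame: metric, node, observed_diff, p, p_fdr, significant.
#' @export
compare_groups <- function(aucs, cohort, covariate_cols = c("age", "sex"),
                           n_perm = 10000L, fdr_q = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- cohort$subject_id
  covs <- if (length(covariate_cols) > 0L)
    as.matrix(cohort[, covariate_cols, drop = FALSE]) else NULL
  out <- list()
  for (m in unique(aucs$metric)) {
    sub <- aucs[aucs$metric == m, , drop = FALSE]
    nodes <- unique(sub$node)
    V <- sapply(nodes, function(nd) {
      rows <- sub[if (is.na(nd)) is.na(sub$node) else
        !is.na(sub$node) & sub$node == nd, , drop = FALSE]
      rows$auc[match(ids, rows$subject_id)]
    })
    V <- matrix(V, nrow = length(ids))
    if (anyNA(V)) stop("AUC table is missing subjects for metric ", m)
    resid <- residualize(V, covs)
    pt <- permutation_test(resid, cohort$group, n_perm = n_perm)
    fdr <- fdr_bh(pt$p_value, q = fdr_q)
    out[[m]] <- data.frame(metric = m, node = as.character(nodes),
                           observed_diff = as.numeric(pt$observed_diff),
                           p = as.numeric(pt$p_value),
                           p_fdr = fdr$p_adjusted,
                           significant = fdr$reject,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Partial correlations between AUC metrics and clinical variables
#'
#' Within one group (default the patients, matching the usual design),
#' correlates each (metric, node) AUC with each clinical variable, partialing
#' out the covariates (default age and sex).
#'
#' @param aucs long AUC data.frame (subject_id, metric, node, auc).
#' @param cohort cohort data.frame.
#' @param clinical_cols character names of clinical variables.
#' @param covariate_cols covariates to partial out (default age, sex).
#' @param group_label restrict to this group (default "patient"; NULL = all).
#' @return data.frame: metric, node, clinical_var, r, p.
#' @export
clinical_correlations <- function(aucs, cohort,
                                  clinical_cols = c("bmi", "hba1c", "glu",
                                                    "chol", "tg", "hdl",
                                                    "ldl", "moca", "duration"),
                                  covariate_cols = c("age", "sex"),
                                  group_label = "patient") {
  if (!is.null(group_label)) cohort <- cohort[cohort$group == group_label, ]
  ids <- cohort$subject_id
  covs <- if (length(covariate_cols) > 0L)
    as.matrix(cohort[, covariate_cols, drop = FALSE]) else NULL
  if (!is.null(covs)) {
    # a covariate constant within the analysed group carries no information
    # and would make every design matrix rank-deficient
    const <- apply(covs, 2, function(x) stats::sd(x) == 0)
    if (any(const)) {
      warning("dropping covariate(s) constant within the group: ",
              paste(colnames(covs)[const], collapse = ", "))
      covs <- covs[, !const, drop = FALSE]
      if (ncol(covs) == 0L) covs <- NULL
    }
  }
  out <- list()
  keys <- unique(aucs[, c("metric", "node")])
  for (i in seq_len(nrow(keys))) {
    m <- keys$metric[i]; nd <- keys$node[i]
    rows <- aucs[aucs$metric == m &
                   (if (is.na(nd)) is.na(aucs$node) else
                     !is.na(aucs$node) & aucs$node == nd), , drop = FALSE]
    vals <- rows$auc[match(ids, rows$subject_id)]
    for (cv in clinical_cols) {
      y <- cohort[[cv]]
      ok <- is.finite(vals) & is.finite(y)
      k <- if (is.null(covs)) 0L else ncol(covs)
      if (sum(ok) <= k + 3L) next
      pc <- tryCatch(partial_correlation(vals[ok], y[ok],
                                         if (is.null(covs)) NULL else
                                           covs[ok, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(pc)) next
      out[[length(out) + 1L]] <- data.frame(metric = m, node = nd,
                                            clinical_var = cv, r = pc$r,
                                            p = pc$p,
                                            stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
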