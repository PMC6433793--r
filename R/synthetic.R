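# Synthetic two-group BOLD cohort generator. Ground truth is a Watts-Strogatz
# small-world graph; regional signals are drawn from a Gaussian graphical
# model whose precision matrix places the coupling on the true edges, then
# band-limited to the low-frequency BOLD band. Group differences are injected
# as extra coupling on the edges incident to designated nodes, and a clinical
# variable can be tied to the per-subject nodal coupling at a target
# correlation.

#' Watts-Strogatz small-world ground-truth network
#'
#' Ring lattice of even degree \code{lattice_degree}, each clockwise edge
#' rewired with probability \code{rewiring_prob} to a uniformly chosen new
#' endpoint (no self-loops or multi-edges). Edge count is conserved exactly.
#' Construction is retried until the graph is connected.
#'
#' @param n_nodes number of nodes (default 90, the AAL-90 parcellation).
#' @param lattice_degree even lattice degree (default 8).
#' @param rewiring_prob rewiring probability in [0, 1] (default 0.1).
#' @param seed optional RNG seed.
#' @param max_retries connectivity retry budget (default 100).
#' @return List of class \code{ground_truth_network} with fields
#'   \code{n_nodes}, \code{adjacency}, \code{rewiring_prob}.
#' @export
make_small_world_graph <- function(n_nodes = 90L, lattice_degree = 8L,
                                   rewiring_prob = 0.1, seed = NULL,
                                   max_retries = 100L) {
  n <- as.integer(n_nodes); k <- as.integer(lattice_degree)
  if (k %% 2L != 0L) stop("lattice_degree must be even")
  if (k >= n) stop("lattice_degree must be smaller than n_nodes")
  if (rewiring_prob < 0 || rewiring_prob > 1) stop("rewiring_prob must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  build <- function() {
    A <- matrix(0L, n, n)
    half <- k %/% 2L
    for (i in seq_len(n)) for (j in seq_len(half)) {
      t <- ((i - 1L + j) %% n) + 1L
      A[i, t] <- 1L; A[t, i] <- 1L
    }
    if (rewiring_prob > 0) {
      for (i in seq_len(n)) for (j in seq_len(half)) {
        t <- ((i - 1L + j) %% n) + 1L
        if (A[i, t] == 1L && stats::runif(1) < rewiring_prob) {
          cand <- which(A[i, ] == 0L & seq_len(n) != i)
          if (length(cand) > 0L) {
            new <- cand[sample.int(length(cand), 1L)]
            A[i, t] <- 0L; A[t, i] <- 0L
            A[i, new] <- 1L; A[new, i] <- 1L
          }
        }
      }
    }
    A
  }
  connected <- function(A) {
    D <- bfs_distances_cpp(A)
    all(D >= 0L)
  }
  for (try in seq_len(max_retries)) {
    A <- build()
    if (connected(A)) {
      return(structure(list(n_nodes = n, adjacency = A,
                            rewiring_prob = rewiring_prob),
                       class = "ground_truth_network"))
    }
  }
  stop("could not produce a connected graph in ", max_retries,
       " attempts (n = ", n, ", k = ", k, ", p = ", rewiring_prob, ")")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat(sprintf("<ground_truth_network> %d nodes, %d edges, rewiring p = %g\n",
              x$n_nodes, sum(x$adjacency) / 2, x$rewiring_prob))
  invisible(x)
}

#' Simulation specification for a synthetic two-group cohort
#'
#' Defaults mirror a typical resting-state study of 55 patients and 47
#' matched controls scanned at TR = 2 s with 200 retained timepoints.
#'
#' @param n_per_group integer vector (patients, controls); default c(55, 47).
#' @param n_timepoints timepoints per subject (default 200).
#' @param tr_seconds sampling interval in seconds (default 2).
#' @param coupling_strength positive scalar placed on every true edge of the
#'   precision matrix (default 0.25).
#' @param noise_sd signal scale (default 1).
#' @param effect_nodes node indices whose incident coupling is raised in the
#'   patient group (default none).
#' @param effect_size additive coupling increment for the patient group
#'   (default 0).
#' @param coupling_jitter_sd SD of the per-subject multiplicative jitter on
#'   the effect nodes' incident coupling (default 0.15); this is the
#'   subject-level "nodal coupling" that a clinical variable can track.
#' @param clinical_assoc optional list(variable =, metric =, r =) tying the
#'   named clinical variable to the subject coupling at target correlation r.
#' @param band band-pass edges in Hz applied to the raw draws
#'   (default c(0.01, 0.08)).
#' @param seed integer seed governing the whole cohort.
#' @return Validated list of class \code{simulation_spec}.
#' @export
simulation_spec <- function(n_per_group = c(55L, 47L), n_timepoints = 200L,
                            tr_seconds = 2, coupling_strength = 0.25,
                            noise_sd = 1, effect_nodes = integer(0),
                            effect_size = 0, coupling_jitter_sd = 0.15,
                            clinical_assoc = NULL, band = c(0.01, 0.08),
                            seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  if (length(n_per_group) != 2L || any(n_per_group < 1L))
    stop("n_per_group must be two positive counts")
  if (n_timepoints < 30L) stop("n_timepoints must be at least 30")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  if (coupling_strength < 0) stop("coupling_strength must be non-negative")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (effect_size < 0) stop("effect_size must be non-negative")
  if (!is.null(clinical_assoc)) {
    if (!all(c("variable", "r") %in% names(clinical_assoc)))
      stop("clinical_assoc needs fields 'variable' and 'r'")
    if (abs(clinical_assoc$r) >= 1) stop("|target correlation| must be < 1")
  }
  structure(list(n_per_group = n_per_group,
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds,
                 coupling_strength = coupling_strength, noise_sd = noise_sd,
                 effect_nodes = as.integer(effect_nodes),
                 effect_size = effect_size,
                 coupling_jitter_sd = coupling_jitter_sd,
                 clinical_assoc = clinical_assoc, band = band,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# Subject-level precision matrix: I + coupling, with the incident coupling of
# the effect nodes scaled by the subject jitter and raised by the group
# effect. A ridge shift restores positive definiteness when the adjacency
# spectrum pushes the smallest eigenvalue below `ridge_floor` (an adjacency
# matrix has negative eigenvalues, so I + cA alone is not PD for every c).
.precision_matrix <- function(gt, spec, group, coupling_scale = 1,
                              ridge_floor = 0.1) {
  A <- gt$adjacency
  W <- spec$coupling_strength * A
  en <- spec$effect_nodes
  if (length(en) > 0L) {
    inc <- matrix(0, nrow(A), ncol(A))
    inc[en, ] <- 1; inc[, en] <- 1
    base <- spec$coupling_strength +
      if (identical(group, "patient")) spec$effect_size else 0
    W[inc > 0 & A > 0] <- coupling_scale * base
  }
  P <- diag(nrow(A)) + W
  lmin <- min(eigen(P, symmetric = TRUE, only.values = TRUE)$values)
  if (lmin < ridge_floor) P <- P + (ridge_floor - lmin) * diag(nrow(A))
  P
}

#' Simulate one subject's band-limited BOLD-like ROI signals
#'
#' Draws T x N Gaussian signals with covariance the inverse of
#' \code{I + coupling_strength * adjacency} (ridge-regularized to stay
#' positive definite), so that true network neighbours have elevated
#' absolute correlation, then band-passes them to the BOLD band. For the
#' patient group the coupling on edges incident to \code{effect_nodes} is
#' raised by \code{effect_size}.
#'
#' @param gt \code{ground_truth_network}.
#' @param spec \code{simulation_spec}.
#' @param group \code{"patient"} or \code{"control"}.
#' @param seed RNG seed for this subject.
#' @param subject_id label for the output.
#' @param coupling_scale per-subject multiplier on the effect nodes' incident
#'   coupling (default 1).
#' @param roi_labels optional labels (default \code{aal90_labels()} when
#'   N = 90).
#' @return \code{roi_timeseries}.
#' @export
simulate_bold <- function(gt, spec, group = c("control", "patient"),
                          seed = 1L, subject_id = "subject",
                          coupling_scale = 1, roi_labels = NULL) {
  stopifnot(inherits(gt, "ground_truth_network"),
            inherits(spec, "simulation_spec"))
  group <- match.arg(group)
  n <- gt$n_nodes
  if (is.null(roi_labels))
    roi_labels <- if (n == 90L) aal90_labels() else paste0("V", seq_len(n))
  set.seed(seed)
  P <- .precision_matrix(gt, spec, group, coupling_scale)
  ch <- tryCatch(chol(P), error = function(e)
    stop("precision matrix not positive definite: ", conditionMessage(e)))
  Sigma <- chol2inv(ch)
  L <- chol(Sigma)
  Z <- matrix(stats::rnorm(spec$n_timepoints * n, sd = spec$noise_sd),
              spec$n_timepoints, n)
  X <- Z %*% L
  ts <- roi_timeseries(X, tr_seconds = spec$tr_seconds,
                       subject_id = subject_id, roi_labels = roi_labels)
  bandpass(ts, spec$band[1], spec$band[2])
}

# truncated normal by rejection (bounds generous relative to sd)
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

#' Generate a full synthetic cohort
#'
#' Produces per-subject ROI time series and a clinical table (group, age,
#' sex, BMI, HbA1c, fasting glucose, lipids, MoCA, disease duration) whose
#' marginals emulate a type-2-diabetes case/control study. When
#' \code{spec$clinical_assoc} is set, that clinical variable is generated as
#' a linear function of the subject's nodal coupling jitter plus noise
#' calibrated so the population correlation equals the target r.
#'
#' @param spec \code{simulation_spec}.
#' @param gt optional \code{ground_truth_network}; default Watts-Strogatz
#'   n = 90, k = 8, p = 0.1 drawn from \code{spec$seed}.
#' @return List with \code{timeseries} (list of \code{roi_timeseries}),
#'   \code{cohort} (data.frame), \code{ground_truth}, and \code{coupling}
#'   (the per-subject jitter vector).
#' @export
make_cohort <- function(spec, gt = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  if (is.null(gt))
    gt <- make_small_world_graph(90L, 8L, 0.1,
                                 seed = sample.int(2^31 - 2, 1))
  n_pat <- spec$n_per_group[1]; n_con <- spec$n_per_group[2]
  n <- n_pat + n_con
  group <- c(rep("patient", n_pat), rep("control", n_con))
  subject_id <- sprintf("sub%03d", seq_len(n))

  # per-subject nodal coupling jitter (the latent the clinical variable tracks)
  u <- .rtruncnorm(n, 1, spec$coupling_jitter_sd, lower = 0.2)
  sim_seeds <- sample.int(2^31 - 2, n)

  is_pat <- group == "patient"
  # demographics and clinical marginals of a typical T2DM case/control table
  age <- .rtruncnorm(n, 53.3, 8.5, 40, 75)
  sex <- integer(n)  # 1 = male, 0 = female
  sex[is_pat]  <- stats::rbinom(n_pat, 1, 35 / 55)
  sex[!is_pat] <- stats::rbinom(n_con, 1, 21 / 47)
  draw2 <- function(mu_p, sd_p, mu_c, sd_c, lower = -Inf) {
    out <- numeric(n)
    out[is_pat]  <- .rtruncnorm(n_pat, mu_p, sd_p, lower)
    out[!is_pat] <- .rtruncnorm(n_con, mu_c, sd_c, lower)
    out
  }
  cohort <- data.frame(
    subject_id = subject_id, group = group, age = age, sex = sex,
    bmi      = draw2(25.37, 2.85, 25.20, 2.80, 15),
    hba1c    = draw2(8.15, 1.78, 5.40, 0.40, 4),   # controls: normal range
    glu      = draw2(9.59, 3.04, 5.10, 0.50, 3),
    chol     = draw2(4.42, 1.10, 4.81, 0.87, 1),
    tg       = draw2(2.05, 2.41, 1.55, 0.82, 0.3),
    hdl      = draw2(0.98, 0.24, 1.21, 0.33, 0.3),
    ldl      = draw2(2.51, 0.90, 2.77, 0.64, 0.5),
    moca     = draw2(25.36, 1.74, 27.79, 1.90, 10),
    duration = ifelse(is_pat, .rtruncnorm(n, 8.87, 6.42, 0.5), 0),
    stringsAsFactors = FALSE)

  ca <- spec$clinical_assoc
  if (!is.null(ca)) {
    if (!ca$variable %in% names(cohort))
      stop("unknown clinical variable: ", ca$variable)
    z_u <- as.numeric(scale(u))
    eps <- stats::rnorm(n)
    base <- cohort[[ca$variable]]
    cohort[[ca$variable]] <- mean(base) +
      stats::sd(base) * (ca$r * z_u + sqrt(1 - ca$r^2) * as.numeric(scale(eps)))
  }

  timeseries <- vector("list", n)
  for (i in seq_len(n)) {
    timeseries[[i]] <- simulate_bold(gt, spec, group = group[i],
                                     seed = sim_seeds[i],
                                     subject_id = subject_id[i],
                                     coupling_scale = u[i])
  }
  names(timeseries) <- subject_id
  list(timeseries = timeseries, cohort = cohort, ground_truth = gt,
       coupling = u)
}
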