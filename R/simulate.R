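# Synthetic two-group cohort generator. Subjects' component timecourses are
# drawn from a ground-truth shared-covariance Gaussian HMM whose transition
# matrix is tilted, in the case group, toward designated "executive" states
# and away from "subcortical/posterior" states; clinical severity, structural
# covariates and motion/QC metrics carry planted correlations with the true
# state occupancy, so every downstream stage of the pipeline has a known
# answer.

#' Specification of a synthetic cohort
#'
#' Collects and validates all generator parameters. Defaults emulate the
#' larger of the two study designs the package targets: 22 controls and 24
#' cases, 30 component channels, 305 volumes at TR 2 s, 8 latent states, a
#' case-group stationary-occupancy shift of 0.1 toward the executive states,
#' a severity score correlating -0.6 with the group-separating occupancy
#' contrast, and structural covariates correlating 0.3 with subcortical-state
#' occupancy.
#'
#' @param n_control,n_case Group sizes (>= 2).
#' @param n_channels Number of component channels C (>= K).
#' @param n_timepoints Series length T (>= 50).
#' @param TR Sampling interval, seconds.
#' @param K Number of latent states.
#' @param delta Case-group shift of stationary mass onto the executive states
#'   (and off the subcortical states).
#' @param delta_sd Between-subject SD of each subject's own shift.
#' @param severity_loading Magnitude of the planted severity correlation.
#' @param structural_loading Planted correlation of structural covariates with
#'   subcortical-state occupancy.
#' @param noise_sd Observation noise SD per channel.
#' @param amplitude Scale of the state mean activation patterns.
#' @param stay_prob Diagonal mass of the base transition matrix.
#' @param executive_states,subcortical_states Disjoint state index sets that
#'   receive (lose) occupancy in cases.
#' @param outlier_fraction Fraction of subjects given outlier-level motion.
#' @param emission `"shared"` (one covariance) or `"per_state"` (a
#'   model-mismatch mode with state-scaled noise).
#' @param noise_model `"iid"` or `"ar1"` (temporally smoothed noise, a
#'   model-mismatch mode).
#' @param seed Integer seed; the cohort is bit-reproducible given the seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 22, n_case = 24, n_channels = 30,
                        n_timepoints = 305, TR = 2, K = 8,
                        delta = 0.1, delta_sd = 0.04,
                        severity_loading = 0.6, structural_loading = 0.3,
                        noise_sd = 0.5, amplitude = 1, stay_prob = 0.78,
                        executive_states = NULL, subcortical_states = NULL,
                        outlier_fraction = 0,
                        emission = c("shared", "per_state"),
                        noise_model = c("iid", "ar1"), seed = 1) {
  emission <- match.arg(emission); noise_model <- match.arg(noise_model)
  if (is.null(executive_states))
    executive_states <- if (K >= 8) c(1L, 4L, 6L) else 1L
  if (is.null(subcortical_states))
    subcortical_states <- if (K >= 8) c(5L, 7L) else 2L
  stopifnot(n_control >= 2, n_case >= 2, n_channels >= K, n_timepoints >= 50,
            TR > 0, K >= 2, delta >= 0, delta_sd >= 0,
            abs(severity_loading) <= 1, abs(structural_loading) <= 1,
            noise_sd > 0, stay_prob > 0, stay_prob < 1,
            outlier_fraction >= 0, outlier_fraction < 0.5)
  if (length(intersect(executive_states, subcortical_states)))
    stop("executive and subcortical state sets must be disjoint")
  if (any(c(executive_states, subcortical_states) > K))
    stop("state index sets exceed K")
  structure(list(n_control = n_control, n_case = n_case,
                 n_channels = n_channels, n_timepoints = n_timepoints,
                 TR = TR, K = K, delta = delta, delta_sd = delta_sd,
                 severity_loading = severity_loading,
                 structural_loading = structural_loading,
                 noise_sd = noise_sd, amplitude = amplitude,
                 stay_prob = stay_prob,
                 executive_states = as.integer(executive_states),
                 subcortical_states = as.integer(subcortical_states),
                 outlier_fraction = outlier_fraction,
                 emission = emission, noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' State mean-activation basis
#'
#' K unit-norm activation patterns over C channels with low pairwise
#' correlation (standing in for ICA spatial-map projections). For K < C the
#' rows are built orthogonal to each other and to the constant vector, so
#' pairwise row correlations are exactly zero; for K = C an orthonormal basis
#' is returned (unit-norm rows, correlations not constrained).
#'
#' @param K Number of states (<= C).
#' @param C Number of channels.
#' @param seed Integer seed.
#' @return K x C matrix with unit-norm rows.
#' @export
make_state_basis <- function(K, C, seed = 1) {
  if (K > C) stop("need at least as many channels as states")
  with_seed(seed, {
    M <- matrix(rnorm(K * C), K, C)
    if (K < C) M <- M - rowMeans(M)          # orthogonal to the constant vector
    # Gram-Schmidt across rows
    for (i in seq_len(K)) {
      v <- M[i, ]
      if (i > 1) for (j in seq_len(i - 1)) v <- v - sum(v * M[j, ]) * M[j, ]
      nv <- sqrt(sum(v^2))
      if (nv < 1e-8) stop("degenerate basis draw; change the seed")
      M[i, ] <- v / nv
    }
    M
  })
}

base_transition <- function(K, stay_prob) {
  P <- matrix((1 - stay_prob) / (K - 1), K, K)
  diag(P) <- stay_prob
  P
}

# Exponentially tilt the columns of a row-stochastic matrix so that the
# stationary mass on `up` states rises by `delta` and on `down` states falls
# by `delta`, solving the two tilting exponents by alternating root-finding.
tilt_transition <- function(base, delta, up, down, tol = 1e-10) {
  check_row_stochastic(base)
  if (delta == 0) return(base)
  pi0 <- stationary_distribution(base)
  target_up <- sum(pi0[up]) + delta
  target_down <- sum(pi0[down]) - delta
  if (target_up >= 1 || target_up <= 0 || target_down <= 0 || target_down >= 1)
    stop("delta = ", delta, " pushes stationary probabilities outside (0,1)")
  apply_tilt <- function(l_up, l_down) {
    W <- base
    W[, up] <- W[, up] * exp(l_up)
    W[, down] <- W[, down] * exp(-l_down)
    W / rowSums(W)
  }
  l_up <- 0; l_down <- 0
  for (it in 1:50) {
    f_up <- function(l) sum(stationary_distribution(apply_tilt(l, l_down))[up]) - target_up
    l_up <- if (abs(f_up(l_up)) < tol) l_up else
      stats::uniroot(f_up, c(-30, 30), tol = 1e-12)$root
    f_down <- function(l) sum(stationary_distribution(apply_tilt(l_up, l))[down]) - target_down
    l_down <- if (abs(f_down(l_down)) < tol) l_down else
      stats::uniroot(f_down, c(-30, 30), tol = 1e-12)$root
    P <- apply_tilt(l_up, l_down)
    pis <- stationary_distribution(P)
    if (abs(sum(pis[up]) - target_up) < tol && abs(sum(pis[down]) - target_down) < tol)
      return(P)
  }
  stop("transition tilting did not converge")
}

#' Group-shifted transition matrix
#'
#' For the case group, exponentially tilts the base transition matrix's
#' columns so that the stationary distribution places `delta` more mass on the
#' executive states and `delta` less on the subcortical states, then
#' renormalizes the rows (which therefore stay stochastic for any feasible
#' `delta`). Controls receive the base matrix unchanged.
#'
#' @param base K x K row-stochastic matrix.
#' @param group `"control"` or `"case"`.
#' @param delta Stationary-mass shift (>= 0).
#' @param executive_states,subcortical_states Disjoint target state sets.
#' @return K x K row-stochastic matrix.
#' @export
sample_transition_matrix <- function(base, group = c("control", "case"),
                                     delta, executive_states,
                                     subcortical_states) {
  group <- match.arg(group)
  if (length(intersect(executive_states, subcortical_states)))
    stop("state sets must be disjoint")
  if (group == "control" || delta == 0) return(base)
  tilt_transition(base, delta, executive_states, subcortical_states)
}

#' Simulate one subject's component timecourses
#'
#' Draws a hidden state path from the subject's transition matrix (started
#' from its stationary distribution) and emits multivariate Gaussian
#' observations around the state means with the shared covariance.
#'
#' @param transition K x K row-stochastic matrix.
#' @param state_means K x C matrix.
#' @param covariance C x C positive-definite matrix.
#' @param n_timepoints Series length.
#' @param seed Integer seed.
#' @param noise_model `"iid"` or `"ar1"`.
#' @return List with `x` (T x C) and `path` (length T).
#' @export
simulate_subject <- function(transition, state_means, covariance,
                             n_timepoints, seed = 1,
                             noise_model = "iid") {
  with_seed(seed, simulate_hmm_series(transition, state_means, covariance,
                                      n_timepoints, noise_model = noise_model))
}

#' Simulate clinical and structural covariates
#'
#' Age is drawn Normal(68, 8) and sex Bernoulli(0.5). The severity score
#' (clinical rating scale: mean 35, SD 13, cases only) is a linear function of each
#' case's true occupancy contrast (executive minus subcortical stationary
#' mass) plus Gaussian noise, scaled so that its correlation with the
#' case-oriented occupancy component (the negated standardized contrast) is
#' approximately `-severity_loading`. Structural covariates (a subcortical
#' volume proxy and a frontal thickness proxy) load positively on
#' subcortical-state occupancy with correlation about `structural_loading`
#' (thickness at half strength).
#'
#' @param true_occupancy n x K matrix of ground-truth stationary occupancies.
#' @param group Character vector (`"control"`/`"case"`), length n.
#' @param severity_loading,structural_loading Planted correlation strengths in
#'   `[-1, 1]`.
#' @param executive_states,subcortical_states State index sets.
#' @param seed Integer seed.
#' @return Data frame: `subject_id`, `group`, `age`, `sex`, `severity` (`NA`
#'   for controls), `subcortical_vol`, `frontal_thickness`.
#' @export
simulate_covariates <- function(true_occupancy, group, severity_loading = 0.6,
                                structural_loading = 0.3,
                                executive_states, subcortical_states,
                                seed = 1) {
  stopifnot(abs(severity_loading) <= 1, abs(structural_loading) <= 1)
  occ <- as.matrix(true_occupancy)
  n <- nrow(occ)
  exec <- rowSums(occ[, executive_states, drop = FALSE])
  subc <- rowSums(occ[, subcortical_states, drop = FALSE])
  contrast <- exec - subc
  is_case <- group == "case"
  with_seed(seed, {
    age <- rnorm(n, 68, 8)
    sex <- rbinom(n, 1, 0.5)
    zs <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
    sev_z <- severity_loading * zs(contrast[is_case]) +
      sqrt(1 - severity_loading^2) * rnorm(sum(is_case))
    severity <- rep(NA_real_, n)
    severity[is_case] <- 35 + 13 * sev_z
    zsub <- zs(subc)
    sv <- structural_loading * zsub +
      sqrt(1 - structural_loading^2) * rnorm(n)
    th <- structural_loading / 2 * zsub +
      sqrt(1 - (structural_loading / 2)^2) * rnorm(n)
    data.frame(subject_id = sprintf("sub%03d", seq_len(n)),
               group = group, age = age, sex = sex, severity = severity,
               subcortical_vol = 50 + 5 * sv,
               frontal_thickness = 2.5 + 0.15 * th)
  })
}

# Rigid-body motion trace: slow AR(1) drift per parameter plus occasional
# spikes; `scale` multiplies both drift and spike size.
simulate_motion_trace <- function(n_timepoints, scale = 1, spike_rate = 0.02) {
  sds <- c(rep(0.02, 3), rep(2e-4, 3)) * scale   # mm, radians per step
  tr <- matrix(0, n_timepoints, 6)
  for (p in 1:6) {
    e <- rnorm(n_timepoints, sd = sds[p])
    tr[, p] <- stats::filter(e, 0.95, method = "recursive")
  }
  spikes <- which(runif(n_timepoints) < spike_rate)
  if (length(spikes))
    tr[spikes, 1:3] <- tr[spikes, 1:3] +
      matrix(rnorm(3 * length(spikes), sd = 0.4 * scale), ncol = 3)
  tr
}

#' Simulate motion traces and QC metrics
#'
#' Generates per-subject rigid-body motion traces (AR(1) drift plus spikes)
#' and a nuisance series, and computes the four quality indices with
#' [qc_metrics()]. A fraction of subjects are planted as motion outliers
#' (drift and spikes inflated fourfold), which the 1-SD [exclusion_rule()]
#' should flag.
#'
#' @param n Number of subjects.
#' @param n_timepoints Volumes per subject.
#' @param outlier_fraction Fraction of subjects planted as outliers (< 0.5).
#' @param seed Integer seed.
#' @param series Optional list of n subject series used for DVARS; a white
#'   nuisance series is simulated when omitted.
#' @return List with `metrics` (data frame, one row per subject), `traces`
#'   (list of T x 6 matrices), and `outliers` (planted outlier indices).
#' @export
simulate_qc_metrics <- function(n, n_timepoints = 305, outlier_fraction = 0,
                                seed = 1, series = NULL) {
  stopifnot(outlier_fraction >= 0, outlier_fraction < 0.5)
  with_seed(seed, {
    n_out <- floor(outlier_fraction * n)
    outliers <- if (n_out > 0) sample.int(n, n_out) else integer(0)
    traces <- vector("list", n)
    mets <- matrix(NA_real_, n, 4)
    for (i in seq_len(n)) {
      sc <- if (i %in% outliers) 4 else 1
      traces[[i]] <- simulate_motion_trace(n_timepoints, scale = sc,
                                           spike_rate = 0.02 * sc)
      x <- if (is.null(series)) matrix(rnorm(n_timepoints * 10), ncol = 10)
           else series[[i]]
      # motion bleeds into the signal so DVARS reflects the planted spikes
      fd <- framewise_displacement(traces[[i]])
      x <- x + fd * sc
      mets[i, ] <- qc_metrics(traces[[i]], x)
    }
    colnames(mets) <- c("max_spike_pct", "median_spike_pct", "max_fd", "max_dvars")
    list(metrics = data.frame(subject_id = sprintf("sub%03d", seq_len(n)), mets),
         traces = traces, outliers = sort(outliers))
  })
}

#' Simulate a two-group cohort with planted effects
#'
#' End-to-end generator: builds the ground-truth HMM (state basis, shared
#' covariance, base transition matrix), gives every subject an individual
#' transition matrix (the group shift `delta` plus subject-level jitter
#' `delta_sd`, applied by exponential tilting), simulates the component
#' timecourses, and generates covariates, motion traces and QC metrics with
#' the planted correlation structure described in [cohort_spec()].
#'
#' @param spec A [cohort_spec()] (or arguments forwarded to it via `...`).
#' @param ... Used to build a spec when `spec` is missing.
#' @return Object of class `synthetic_cohort`: `timeseries` (list of T x C
#'   matrices), `covariates`, `qc` (metrics, traces, outliers), and
#'   `ground_truth` (basis, covariance, per-subject transitions, hidden paths,
#'   true occupancies), plus the `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec(...), ...) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_control + spec$n_case
  group <- rep(c("control", "case"), c(spec$n_control, spec$n_case))
  basis <- make_state_basis(spec$K, spec$n_channels, seed = spec$seed)
  means <- spec$amplitude * basis
  covariance <- diag(spec$noise_sd^2, spec$n_channels)
  state_cov_scale <- if (spec$emission == "per_state")
    seq(0.7, 1.3, length.out = spec$K) else NULL
  base <- base_transition(spec$K, spec$stay_prob)
  pi0 <- stationary_distribution(base)
  max_up <- sum(pi0[-spec$executive_states]) - 1e-3
  max_down <- sum(pi0[spec$subcortical_states]) - 1e-3

  out <- with_seed(spec$seed, {
    deltas <- (group == "case") * spec$delta + rnorm(n, 0, spec$delta_sd)
    deltas <- pmin(pmax(deltas, -max_down / 2), min(max_up, max_down))
    transitions <- lapply(deltas, function(d) {
      if (abs(d) < 1e-12) base
      else if (d > 0) tilt_transition(base, d, spec$executive_states,
                                      spec$subcortical_states)
      else tilt_transition(base, -d, spec$subcortical_states,
                           spec$executive_states)
    })
    true_occ <- t(vapply(transitions, stationary_distribution, numeric(spec$K)))
    timeseries <- vector("list", n)
    paths <- vector("list", n)
    for (i in seq_len(n)) {
      sim <- simulate_hmm_series(transitions[[i]], means, covariance,
                                 spec$n_timepoints,
                                 noise_model = spec$noise_model,
                                 state_cov_scale = state_cov_scale)
      timeseries[[i]] <- sim$x
      paths[[i]] <- sim$path
    }
    list(deltas = deltas, transitions = transitions, true_occ = true_occ,
         timeseries = timeseries, paths = paths)
  })
  names(out$timeseries) <- sprintf("sub%03d", seq_len(n))

  covariates <- simulate_covariates(out$true_occ, group,
                                    spec$severity_loading,
                                    spec$structural_loading,
                                    spec$executive_states,
                                    spec$subcortical_states,
                                    seed = spec$seed + 1L)
  qc <- simulate_qc_metrics(n, spec$n_timepoints, spec$outlier_fraction,
                            seed = spec$seed + 2L, series = out$timeseries)

  structure(list(timeseries = out$timeseries, covariates = covariates,
                 qc = qc,
                 ground_truth = list(state_means = means,
                                     shared_covariance = covariance,
                                     base_transition = base,
                                     per_subject_transition = out$transitions,
                                     per_subject_delta = out$deltas,
                                     per_subject_hidden_path = out$paths,
                                     true_occupancy = out$true_occ),
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Synthetic cohort: %d controls + %d cases, C=%d, T=%d, K=%d states\n",
              s$n_control, s$n_case, s$n_channels, s$n_timepoints, s$K))
  cat(sprintf("  occupancy shift %.3g (executive: %s; subcortical: %s), severity loading %.2g\n",
              s$delta, paste(s$executive_states, collapse = ","),
              paste(s$subcortical_states, collapse = ","), s$severity_loading))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' One tab-delimited timecourse file per subject (channels as columns, header
#' row), a covariate TSV, a QC TSV, and a ground-truth JSON.
#'
#' @param cohort A [simulate_cohort()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ts_dir <- file.path(dir, "timeseries")
  dir.create(ts_dir, showWarnings = FALSE)
  paths <- character(0)
  for (id in names(cohort$timeseries)) {
    p <- file.path(ts_dir, paste0(id, ".tsv"))
    m <- cohort$timeseries[[id]]
    colnames(m) <- paste0("ch", seq_len(ncol(m)))
    io_write_table(as.data.frame(m), p)
    paths <- c(paths, p)
  }
  pcov <- file.path(dir, "covariates.tsv")
  io_write_table(cohort$covariates, pcov)
  pqc <- file.path(dir, "qc.tsv")
  io_write_table(cohort$qc$metrics, pqc)
  pgt <- file.path(dir, "ground_truth.json")
  gt <- cohort$ground_truth
  jsonlite::write_json(list(state_means = gt$state_means,
                            shared_covariance = gt$shared_covariance,
                            per_subject_transition = gt$per_subject_transition,
                            true_occupancy = gt$true_occupancy,
                            seed = cohort$spec$seed),
                       pgt, digits = NA)
  invisible(c(paths, pcov, pqc, pgt))
}
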