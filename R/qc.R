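# Motion and image-quality metrics, the 1-SD exclusion rule, and the
# composite motion covariate.

#' Framewise displacement from rigid-body motion parameters
#'
#' `FD_t = sum |delta translation| + head_radius * sum |delta rotation|`, with
#' translations in mm, rotations in radians converted to arc length at the
#' given head radius; the first volume has FD 0.
#'
#' @param trace T x 6 matrix: three translations (mm) then three rotations
#'   (radians).
#' @param head_radius Assumed head radius in mm (default 50).
#' @return Length-T non-negative vector.
#' @export
framewise_displacement <- function(trace, head_radius = 50) {
  trace <- as.matrix(trace)
  if (ncol(trace) != 6) stop("motion trace must have 6 columns")
  if (any(!is.finite(trace))) stop("non-finite motion parameters")
  d <- abs(diff(trace))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius * rowSums(d[, 4:6, drop = FALSE]))
}

#' DVARS of a multichannel series
#'
#' Root-mean-square across channels of the volume-to-volume signal difference;
#' the first volume has DVARS 0.
#'
#' @param x Timepoints x channels matrix.
#' @return Length-T non-negative vector.
#' @export
dvars <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 volumes")
  c(0, sqrt(rowMeans(diff(x)^2)))
}

#' Spike percentage
#'
#' Percentage of volumes whose framewise displacement or DVARS exceeds its
#' threshold.
#'
#' @param fd,dv Per-volume FD and DVARS series (equal length).
#' @param fd_thresh FD threshold in mm (default 0.5).
#' @param dvars_thresh DVARS threshold; default 1.5 x the series median.
#' @return Percentage in `[0, 100]`.
#' @export
spike_percentage <- function(fd, dv, fd_thresh = 0.5,
                             dvars_thresh = 1.5 * median(dv[-1])) {
  stopifnot(length(fd) == length(dv), fd_thresh > 0, dvars_thresh > 0)
  100 * mean(fd > fd_thresh | dv > dvars_thresh)
}

#' Per-subject quality-control metrics
#'
#' Computes the four exclusion indices from a subject's motion trace and
#' component series: maximum spike percentage (over a sliding window),
#' median spike percentage, maximum framewise displacement, and maximum DVARS.
#' Spike percentages are computed per contiguous window so that the maximum
#' and the median are distinct summaries of the spike distribution over the
#' scan.
#'
#' @param trace T x 6 motion parameters.
#' @param x Timepoints x channels series.
#' @param window Window length (volumes) for spike-percentage summaries.
#' @param fd_thresh,dvars_thresh Spike thresholds (see [spike_percentage()]).
#' @return Named vector: `max_spike_pct`, `median_spike_pct`, `max_fd`,
#'   `max_dvars`.
#' @export
qc_metrics <- function(trace, x, window = 50, fd_thresh = 0.5,
                       dvars_thresh = NULL) {
  fd <- framewise_displacement(trace)
  dv <- dvars(x)
  if (is.null(dvars_thresh)) dvars_thresh <- 1.5 * median(dv[-1])
  T <- length(fd)
  starts <- seq(1, max(T - window + 1, 1), by = window)
  spikes <- vapply(starts, function(s) {
    idx <- s:min(s + window - 1, T)
    spike_percentage(fd[idx], dv[idx], fd_thresh, dvars_thresh)
  }, 1)
  c(max_spike_pct = max(spikes), median_spike_pct = median(spikes),
    max_fd = max(fd), max_dvars = max(dv))
}

#' 1-SD quality exclusion rule
#'
#' A subject is excluded when any metric exceeds the reference sample mean
#' plus one reference sample standard deviation of that metric (all four
#' indices are worse-when-larger, so the rule is one-sided). The reference
#' statistics default to the supplied table but can be overridden by an
#' external reference (e.g. a large normative sample).
#'
#' @param metrics Data frame or matrix of per-subject metrics (subjects x
#'   metrics, numeric columns only).
#' @param reference Optional list with `mean` and `sd` vectors (named as the
#'   metric columns) replacing the within-sample statistics.
#' @return List with `excluded` (logical per subject), `thresholds`, and
#'   `report` (data frame with per-subject flags and the offending metrics).
#' @export
exclusion_rule <- function(metrics, reference = NULL) {
  m <- as.matrix(as.data.frame(metrics))
  if (nrow(m) < 3 && is.null(reference)) stop("need at least 3 subjects")
  mu <- if (is.null(reference)) colMeans(m) else reference$mean[colnames(m)]
  s <- if (is.null(reference)) apply(m, 2, sd) else reference$sd[colnames(m)]
  thr <- mu + s
  over <- sweep(m, 2, thr, ">")
  excluded <- apply(over, 1, any)
  report <- data.frame(subject = rownames(m) %||% seq_len(nrow(m)),
                       excluded = excluded,
                       reason = apply(over, 1, function(r)
                         paste(colnames(m)[r], collapse = ";")))
  list(excluded = excluded, thresholds = thr, report = report)
}

#' Composite motion covariate
#'
#' Each metric is z-scored across subjects and the four standardized metrics
#' are averaged within subject, yielding a single nuisance covariate with
#' sample mean 0. Zero-variance metrics are dropped with a warning.
#'
#' @param metrics Subjects x metrics table.
#' @return Numeric vector (one value per subject, mean 0).
#' @export
motion_covariate <- function(metrics) {
  m <- as.matrix(as.data.frame(metrics))
  if (nrow(m) < 2) stop("need at least 2 subjects")
  keep <- apply(m, 2, sd) > 0
  if (!all(keep)) warning("zero-variance metric(s) dropped: ",
                          paste(colnames(m)[!keep], collapse = ", "))
  if (!any(keep)) return(rep(0, nrow(m)))
  rowMeans(scale(m[, keep, drop = FALSE]))
}
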