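# Per-subject temporal metrics of the latent state sequence, and state
# matching between independently fitted models.

#' Fractional occupancy from posterior state probabilities
#'
#' The proportion of scan time each state is active: column means of the
#' posterior probability matrix. Compositional (sums to 1 across states).
#'
#' @param gamma T x K matrix with non-negative rows summing to 1.
#' @return Length-K vector summing to 1.
#' @export
fractional_occupancy <- function(gamma) {
  gamma <- as.matrix(gamma)
  if (any(gamma < -1e-10) || any(abs(rowSums(gamma) - 1) > 1e-8))
    stop("gamma rows must be probabilities summing to 1")
  colMeans(gamma)
}

#' Switching rate of a state path
#'
#' Number of state transitions per volume pair: the fraction of consecutive
#' volume pairs whose decoded states differ. 0 for a constant path, 1 for a
#' strictly alternating one.
#'
#' @param path Integer state path of length >= 2.
#' @return Scalar in `[0, 1]`.
#' @export
switching_rate <- function(path) {
  if (length(path) < 2) stop("path must have at least 2 volumes")
  mean(path[-1] != path[-length(path)])
}

#' Mean state lifetimes of a path
#'
#' Mean dwell time (in volumes) of each state's visits; `NA` for unvisited
#' states.
#'
#' @param path Integer state path.
#' @param K Number of states.
#' @return Length-K vector of mean dwell times.
#' @export
mean_lifetime <- function(path, K = max(path)) {
  r <- rle(path)
  vapply(seq_len(K), function(k) {
    d <- r$lengths[r$values == k]
    if (length(d)) mean(d) else NA_real_
  }, 1)
}

#' Per-subject temporal metrics from a fitted model
#'
#' Fractional occupancy is computed from the soft posteriors (`gamma`) by
#' default; switching rate and lifetimes from the Viterbi path. Occupancy can
#' instead be computed from the hard path with `fo_from = "viterbi"`.
#'
#' @param object A fitted [fit_hmm()] object.
#' @param fo_from `"gamma"` (default) or `"viterbi"`.
#' @return List with `fo` (subjects x K matrix), `switching_rate` (vector),
#'   `mean_lifetime` (subjects x K), `paths`, and `subject_ids`.
#' @export
state_metrics <- function(object, fo_from = c("gamma", "viterbi")) {
  fo_from <- match.arg(fo_from)
  stopifnot(inherits(object, "ghmm"))
  n <- length(object$subject_ids)
  paths <- predict(object, type = "viterbi")
  fo <- t(vapply(seq_len(n), function(s) {
    if (fo_from == "gamma") fractional_occupancy(object$gamma[[s]])
    else tabulate(paths[[s]], object$K) / length(paths[[s]])
  }, numeric(object$K)))
  sw <- vapply(paths, switching_rate, 1)
  lt <- t(vapply(paths, mean_lifetime, numeric(object$K), K = object$K))
  colnames(fo) <- colnames(lt) <- paste0("state", seq_len(object$K))
  list(fo = fo, switching_rate = sw, mean_lifetime = lt, paths = paths,
       subject_ids = object$subject_ids)
}

#' Dice coefficient of two binary maps
#'
#' `2|A and B| / (|A| + |B|)`; 0 by convention (with a warning) when both maps
#' are empty.
#'
#' @param a,b Logical or 0/1 vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("maps must have equal length")
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    warning("both maps empty; Dice defined as 0")
    return(0)
  }
  2 * sum(a & b) / denom
}

#' Match states between two fitted models
#'
#' Finds the one-to-one assignment of model B's states to model A's that
#' maximizes the total similarity of their mean activation maps. Similarity is
#' the Dice coefficient of maps binarized at `|mean activation| >
#' threshold_sd` standard deviations of each map (matching positive and
#' negative activation separately and averaging), with the Pearson correlation
#' of the raw maps used to break ties. The assignment is exact (all
#' permutations are scored for K <= 9; a greedy fallback is used above that).
#'
#' @param model_a,model_b Fitted `ghmm` objects (or lists with `means`) with
#'   equal K.
#' @param threshold_sd Binarization threshold in SD units of each map.
#' @return List with `permutation` (index p such that B's state `p[k]` matches
#'   A's state k), `dice` (per matched pair), and `correlation` (raw-map
#'   Pearson r per pair).
#' @export
match_states <- function(model_a, model_b, threshold_sd = 0.5) {
  A <- as.matrix(model_a$means); B <- as.matrix(model_b$means)
  if (!all(dim(A) == dim(B))) stop("models must have the same K and C")
  K <- nrow(A)
  binmap <- function(m) {
    s <- sd(m)
    list(pos = m > threshold_sd * s, neg = m < -threshold_sd * s)
  }
  dice_pair <- function(i, j) {
    ba <- binmap(A[i, ]); bb <- binmap(B[j, ])
    suppressWarnings(mean(c(dice_coefficient(ba$pos, bb$pos),
                            dice_coefficient(ba$neg, bb$neg))))
  }
  D <- outer(seq_len(K), seq_len(K), Vectorize(dice_pair))
  R <- cor(t(A), t(B))
  score <- D + 1e-6 * R   # correlation as tie-break only
  perm <- best_assignment(score)
  list(permutation = perm,
       dice = D[cbind(seq_len(K), perm)],
       correlation = R[cbind(seq_len(K), perm)])
}

# Exact linear assignment by permutation enumeration for small K,
# greedy otherwise (K here is 8 in practice).
best_assignment <- function(score) {
  K <- nrow(score)
  if (K <= 9) {
    perms <- permutations_of(K)
    vals <- vapply(perms, function(p) sum(score[cbind(seq_len(K), p)]), 1)
    perms[[which.max(vals)]]
  } else {
    perm <- integer(K)
    avail <- rep(TRUE, K)
    for (i in order(apply(score, 1, max), decreasing = TRUE)) {
      j <- which(avail)[which.max(score[i, avail])]
      perm[i] <- j
      avail[j] <- FALSE
    }
    perm
  }
}

permutations_of <- function(K) {
  if (K == 1) return(list(1L))
  sub <- permutations_of(K - 1L)
  out <- vector("list", K * length(sub))
  i <- 0L
  for (p in sub) for (pos in 0:(K - 1L)) {   # insert K at each position
    i <- i + 1L
    out[[i]] <- append(p, K, after = pos)
  }
  out
}

#' Stage-1 dual regression
#'
#' Given group spatial maps (components x voxels) and one subject's data
#' (timepoints x voxels), regresses every volume on the maps to obtain that
#' subject's component timecourses: row t of the result holds the
#' least-squares coefficients of volume t on the maps.
#'
#' @param maps C x V matrix of spatial maps, full row rank, C < V.
#' @param data T x V subject data matrix.
#' @return T x C matrix of component timecourses.
#' @export
dual_regression_stage1 <- function(maps, data) {
  maps <- as.matrix(maps); data <- as.matrix(data)
  if (ncol(maps) != ncol(data)) stop("maps and data must share the voxel dimension")
  if (nrow(maps) >= ncol(maps)) stop("need more voxels than maps")
  G <- tcrossprod(maps)   # C x C
  if (rcond(G) < 1e-12) stop("spatial maps are rank deficient")
  data %*% t(maps) %*% solve(G)
}
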