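# Density-thresholded graphs from association matrices, topology metrics,
# and degree-preserving random-graph normalization. Standard graph algorithms
# are delegated to igraph; thresholding, normalization and the regional
# summaries are implemented here.

#' Density-threshold an association matrix
#'
#' Retains the `round(density * R(R-1)/2)` strongest edges of a symmetric
#' association matrix, ranked by signed correlation (most positive first) by
#' default, or by absolute value with `rank_by = "absolute"`. Ties are broken
#' by node-index order (row, then column) with a message.
#'
#' @param mat Symmetric R x R association matrix.
#' @param density Fraction of possible edges to keep, in (0, 1].
#' @param rank_by `"signed"` (default) or `"absolute"`.
#' @return List with `adjacency` (binary R x R), `weighted` (retained weights,
#'   0 elsewhere), `n_edges`, `density`.
#' @export
threshold_density <- function(mat, density = 0.05, rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  mat <- as.matrix(mat)
  R <- nrow(mat)
  if (R != ncol(mat) || max(abs(mat - t(mat))) > 1e-10)
    stop("association matrix must be symmetric")
  stopifnot(density > 0, density <= 1)
  ut <- which(upper.tri(mat), arr.ind = TRUE)
  w <- mat[upper.tri(mat)]
  key <- if (rank_by == "signed") w else abs(w)
  m <- round(density * R * (R - 1) / 2)
  if (m < 1) stop("density ", density, " retains no edges at R = ", R)
  ord <- order(-key, ut[, 1], ut[, 2])   # ties broken by node index order
  if (m < length(key)) {
    kth <- key[ord[m]]
    if (sum(key == kth) > 1)
      message("ties at the density cutoff broken by node-index order")
  }
  keep <- ord[seq_len(m)]
  adj <- matrix(0L, R, R); wt <- matrix(0, R, R)
  ii <- ut[keep, , drop = FALSE]
  adj[ii] <- 1L; adj[ii[, 2:1, drop = FALSE]] <- 1L
  wt[ii] <- w[keep]; wt[ii[, 2:1, drop = FALSE]] <- w[keep]
  dimnames(adj) <- dimnames(wt) <- dimnames(mat)
  list(adjacency = adj, weighted = wt, n_edges = m, density = density)
}

as_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected", diag = FALSE)
}

#' Clustering coefficient of a binary graph
#'
#' Per-node proportion of closed triangles among the node's neighbour pairs
#' (`2 * triangles / (k (k - 1))`); nodes with degree < 2 contribute 0.
#'
#' @param adj Binary adjacency matrix or igraph graph.
#' @return List with `per_node` and `mean`.
#' @export
clustering_coefficient <- function(adj) {
  g <- if (inherits(adj, "igraph")) adj else as_igraph(adj)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  list(per_node = cc, mean = mean(cc))
}

#' Characteristic path length of a binary graph
#'
#' Mean shortest-path length over all reachable ordered node pairs;
#' unreachable pairs are excluded and their fraction reported (a message is
#' emitted when any are excluded).
#'
#' @param adj Binary adjacency matrix or igraph graph.
#' @return List with `mean` and `excluded_fraction`.
#' @export
char_path_length <- function(adj) {
  g <- if (inherits(adj, "igraph")) adj else as_igraph(adj)
  d <- igraph::distances(g)
  off <- d[row(d) != col(d)]
  reach <- is.finite(off)
  if (!any(reach)) stop("no reachable node pairs")
  excl <- mean(!reach)
  if (excl > 0)
    message(sprintf("%.1f%% of node pairs unreachable; excluded from path length",
                    100 * excl))
  list(mean = mean(off[reach]), excluded_fraction = excl)
}

#' Degree-preserving graph randomization
#'
#' Rewires a binary graph by double-edge swaps, preserving every node's degree
#' exactly while randomizing the topology; used to build the null ensemble
#' against which clustering and path length are normalized.
#'
#' @param adj Binary adjacency matrix or igraph graph.
#' @param n_swaps Number of attempted swaps; default `10 * |E|`.
#' @param seed Integer seed.
#' @return Rewired graph in the same representation as the input.
#' @export
degree_preserving_randomize <- function(adj, n_swaps = NULL, seed = 1) {
  was_matrix <- !inherits(adj, "igraph")
  g <- if (was_matrix) as_igraph(adj) else adj
  ne <- igraph::ecount(g)
  if (ne < 2) return(adj)
  if (is.null(n_swaps)) n_swaps <- 10 * ne
  rg <- with_seed(seed, igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps)))
  if (!was_matrix) return(rg)
  out <- as.matrix(igraph::as_adjacency_matrix(rg, sparse = FALSE))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(adj)
  out
}

#' Normalize an observed metric against a null ensemble
#'
#' @param observed Scalar metric of the observed graph.
#' @param null_values Metric values over the null ensemble.
#' @return `observed / mean(null_values)`.
#' @export
normalize_metric <- function(observed, null_values) {
  if (length(null_values) < 1) stop("empty null ensemble")
  m <- mean(null_values)
  if (!is.finite(m) || m == 0) stop("null ensemble mean is zero or non-finite")
  observed / m
}

#' Graph topology metrics with null normalization
#'
#' Thresholds an association matrix at the given density, computes weighted
#' degree (on the retained weighted matrix), mean clustering coefficient and
#' characteristic path length (on the binarized graph), and normalizes the
#' latter two against an ensemble of degree-preserving random graphs
#' (observed / null mean). Normalized clustering well above 1 with normalized
#' path length near 1 indicates small-world topology; both near 1 indicates a
#' random-like network.
#'
#' @param mat Symmetric association matrix.
#' @param density Edge density retained (default 0.05).
#' @param n_null Null ensemble size (default 1000).
#' @param seed Integer seed for the null ensemble.
#' @param rank_by Edge ranking passed to [threshold_density()].
#' @return List with `weighted_degree` (per node), `clustering_raw`,
#'   `clustering_normalized`, `path_length_raw`, `path_length_normalized`,
#'   `density`, `n_null`, and the `thresholded` matrices.
#' @export
graph_metrics <- function(mat, density = 0.05, n_null = 1000, seed = 1,
                          rank_by = "signed") {
  th <- threshold_density(mat, density, rank_by = rank_by)
  g <- as_igraph(th$adjacency)
  cc <- clustering_coefficient(g)$mean
  pl <- suppressMessages(char_path_length(g)$mean)
  null_cc <- numeric(n_null); null_pl <- numeric(n_null)
  for (b in seq_len(n_null)) {
    rg <- degree_preserving_randomize(g, seed = seed + b - 1L)
    null_cc[b] <- clustering_coefficient(rg)$mean
    null_pl[b] <- suppressMessages(char_path_length(rg)$mean)
  }
  list(weighted_degree = rowSums(th$weighted),
       clustering_raw = cc,
       clustering_normalized = normalize_metric(cc, null_cc),
       path_length_raw = pl,
       path_length_normalized = normalize_metric(pl, null_pl),
       density = density, n_null = n_null, thresholded = th)
}

#' Regional mean weighted degree
#'
#' Weighted degree (sum of retained incident edge weights) per node, averaged
#' within each region of a node partition (e.g. cortical vs subcortical).
#'
#' @param weighted Retained weighted matrix from [threshold_density()].
#' @param partition Factor or character vector assigning every node a region.
#' @return Named vector of regional mean weighted degrees.
#' @export
regional_weighted_degree <- function(weighted, partition) {
  weighted <- as.matrix(weighted)
  if (length(partition) != nrow(weighted))
    stop("partition must label every node")
  partition <- as.factor(partition)
  if (any(table(partition) == 0)) stop("empty region in partition")
  deg <- rowSums(weighted)
  tapply(deg, partition, mean)
}
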