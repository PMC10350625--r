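#' Unpooling configuration
#'
#' @param method `"isotropic"` (copy the coarse feature to every cluster
#'   member), `"proportional"` (redistribute the coarse feature with weights
#'   proportional to the stored fine snapshot) or `"knn"` (inverse square
#'   distance interpolation from the k nearest coarse nodes).
#' @param k neighbor count for `knn` (default 3).
#' @param epsilon small positive constant guarding divisions.
#' @return An object of class `unpool_config`.
#' @export
unpool_config <- function(method = c("isotropic", "proportional", "knn"),
                          k = 3L, epsilon = 1e-8) {
  method <- match.arg(method)
  if (k < 1L) stop("k must be >= 1")
  if (epsilon <= 0) stop("epsilon must be positive")
  structure(list(method = method, k = as.integer(k), epsilon = epsilon),
            class = "unpool_config")
}

#' Isotropic unpooling
#'
#' Restores the fine topology by copying each coarse node's feature to every
#' member of its cluster.
#'
#' @param coarse_features numeric `N_coarse x C` matrix (or vector).
#' @param record the [pool_record()] emitted at pooling time.
#' @return Numeric `N_fine x C` matrix.
#' @export
isotropic_unpool <- function(coarse_features, record) {
  coarse_features <- as.matrix(coarse_features)
  cl <- record$cluster_of
  if (nrow(coarse_features) != nrow(record$coarse_positions))
    stop("coarse feature count does not match the record")
  if (anyNA(cl))
    stop("record contains dropped nodes; use knn unpooling")
  coarse_features[cl, , drop = FALSE]
}

isotropic_unpool_backward <- function(g_fine, record) {
  rowsum_into(as.matrix(g_fine), record$cluster_of,
              nrow(record$coarse_positions))
}

# Redistribution weights p_i = stored_i / sum(stored over cluster), one
# column per channel when the stored snapshot matches the feature width,
# otherwise a single column from the snapshot row-means (the scalar rule).
# Clusters whose stored sum is below epsilon in magnitude fall back to
# uniform weights 1/|cluster|.
proportional_weights <- function(record, n_channels, epsilon) {
  stored <- as.matrix(record$stored_fine_features)
  if (ncol(stored) != n_channels)
    stored <- matrix(rowMeans(stored), ncol = 1)
  cl <- record$cluster_of
  nc <- nrow(record$coarse_positions)
  sums <- rowsum_into(stored, cl, nc)
  sizes <- tabulate(cl, nc)
  p <- matrix(0, nrow(stored), ncol(stored))
  for (j in seq_len(ncol(stored))) {
    s <- sums[cl, j]
    fallback <- abs(s) < epsilon
    p[, j] <- ifelse(fallback, 1 / sizes[cl], stored[, j] / s)
  }
  p
}

#' Proportional unpooling
#'
#' Redistributes each coarse feature over its cluster members with weights
#' `p_i = v_i / sum_{j in cluster} v_j` computed from the snapshot of fine
#' features stored at pooling time, so the members of a cluster sum back to
#' the coarse value.  The weights are treated as constants under
#' differentiation: gradient flows only through the coarse features.
#' Clusters whose stored sum is smaller than `epsilon` in magnitude fall
#' back to uniform weights.
#'
#' @inheritParams isotropic_unpool
#' @param config an [unpool_config()] (only `epsilon` is used).
#' @return Numeric `N_fine x C` matrix.
#' @export
proportional_unpool <- function(coarse_features, record,
                                config = unpool_config("proportional")) {
  coarse_features <- as.matrix(coarse_features)
  if (is.null(record$stored_fine_features))
    stop("record lacks the stored fine-feature snapshot")
  if (anyNA(record$cluster_of))
    stop("record contains dropped nodes; use knn unpooling")
  p <- proportional_weights(record, ncol(coarse_features), config$epsilon)
  fine <- coarse_features[record$cluster_of, , drop = FALSE]
  if (ncol(p) == 1L) p <- p[, rep(1L, ncol(fine)), drop = FALSE]
  fine * p
}

proportional_unpool_backward <- function(g_fine, record, n_channels,
                                         epsilon = 1e-8) {
  g_fine <- as.matrix(g_fine)
  p <- proportional_weights(record, n_channels, epsilon)
  if (ncol(p) == 1L) p <- p[, rep(1L, ncol(g_fine)), drop = FALSE]
  rowsum_into(g_fine * p, record$cluster_of,
              nrow(record$coarse_positions))
}

# Tie-inclusive k nearest coarse nodes per fine node: all coarse nodes whose
# distance ties the k-th nearest are included, so the interpolation is
# invariant to node relabeling even on regular grids.
knn_edges <- function(fine_positions, coarse_positions, k, epsilon) {
  nf <- nrow(fine_positions)
  nc <- nrow(coarse_positions)
  k <- min(k, nc)
  d2 <- outer(rowSums(fine_positions^2), rep(1, nc)) +
    outer(rep(1, nf), rowSums(coarse_positions^2)) -
    2 * fine_positions %*% t(coarse_positions)
  d2 <- pmax(d2, 0)
  fi <- integer(0); ci <- integer(0); w <- numeric(0)
  for (i in seq_len(nf)) {
    kth <- sort(d2[i, ], partial = k)[k]
    sel <- which(d2[i, ] <= kth + 1e-12)
    wi <- 1 / (d2[i, sel] + epsilon)
    fi <- c(fi, rep.int(i, length(sel)))
    ci <- c(ci, sel)
    w <- c(w, wi / sum(wi))
  }
  list(fine = fi, coarse = ci, w = w, n_fine = nf, n_coarse = nc)
}

#' kNN interpolation unpooling
#'
#' Each fine node receives the weighted sum of its k nearest coarse nodes by
#' Euclidean position, with weights inversely proportional to the squared
#' distance (`w_j = 1 / (d_j^2 + epsilon)`, normalized to sum to 1).  Coarse
#' nodes tied with the k-th nearest distance are all included.  If fewer
#' than k coarse nodes exist, all are used.
#'
#' @param coarse_features numeric `N_coarse x C` matrix (or vector).
#' @param coarse_positions numeric `N_coarse x 2`.
#' @param fine_positions numeric `N_fine x 2`.
#' @param config an [unpool_config()].
#' @return Numeric `N_fine x C` matrix.
#' @export
knn_unpool <- function(coarse_features, coarse_positions, fine_positions,
                       config = unpool_config("knn")) {
  coarse_features <- as.matrix(coarse_features)
  if (nrow(coarse_features) < 1L) stop("need at least one coarse node")
  ke <- knn_edges(as.matrix(fine_positions), as.matrix(coarse_positions),
                  config$k, config$epsilon)
  contrib <- coarse_features[ke$coarse, , drop = FALSE] * ke$w
  rowsum_into(contrib, ke$fine, ke$n_fine)
}

knn_unpool_backward <- function(g_fine, ke) {
  g_fine <- as.matrix(g_fine)
  rowsum_into(g_fine[ke$fine, , drop = FALSE] * ke$w, ke$coarse,
              ke$n_coarse)
}
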