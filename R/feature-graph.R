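#' Feature graph
#'
#' The carrier of all network computation: a set of nodes with multi-channel
#' features, 2-D positions, a symmetric directed edge list and per-edge
#' geometric pseudo-coordinates in `[0,1]^2`.
#'
#' Positions use the 0-based `(row, col)` convention with rows increasing
#' downward.  The pseudo-coordinate of a directed edge `i -> j` is the
#' relative displacement `pos_j - pos_i` mapped affinely per component from
#' `[-d_max, +d_max]` to `[0, 1]`, so that
#' `pseudo(i->j) + pseudo(j->i) = (1, 1)`.
#'
#' @param x numeric `N x C` feature matrix.
#' @param pos numeric `N x 2` positions (row, col), 0-based.
#' @param edges integer `E x 2` matrix of directed edges `(src, dst)`,
#'   1-based node indices.  Must be symmetric as a set.
#' @param pseudo numeric `E x 2` pseudo-coordinates in `[0,1]^2`; computed
#'   from `pos` and `d_max` when `NULL`.
#' @param d_max scalar normalization half-range for displacements.
#' @param pixel_index integer `N x 2` (row, col) 1-based indices mapping
#'   nodes back to the source slice, or `NULL` for free graphs.
#' @param slice_meta list with `case_id`, `slice_index`, `shape`.
#' @param check validate invariants (symmetry, ranges); disable for trusted
#'   internal construction.
#' @return An object of class `feature_graph`.
#' @export
feature_graph <- function(x, pos, edges, pseudo = NULL, d_max = 1,
                          pixel_index = NULL, slice_meta = NULL,
                          check = TRUE) {
  x <- as.matrix(x)
  pos <- as.matrix(pos)
  edges <- matrix(as.integer(edges), ncol = 2)
  n <- nrow(x)
  if (nrow(pos) != n) stop("pos/features row mismatch")
  if (nrow(edges) && (min(edges) < 1L || max(edges) > n))
    stop("edge endpoint out of range")
  if (is.null(pseudo)) {
    pseudo <- compute_pseudo(pos, edges, d_max)
  } else {
    pseudo <- as.matrix(pseudo)
  }
  if (check && nrow(edges)) {
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    key <- function(a, b) paste(a, b)
    if (!setequal(key(edges[, 1], edges[, 2]), key(edges[, 2], edges[, 1])))
      stop("edge set is not symmetric")
    if (min(pseudo) < -1e-9 || max(pseudo) > 1 + 1e-9)
      stop("pseudo-coordinates outside [0,1]")
  }
  if (!is.null(pixel_index)) {
    pixel_index <- matrix(as.integer(pixel_index), ncol = 2)
    if (check && anyDuplicated(paste(pixel_index[, 1], pixel_index[, 2])))
      stop("pixel_index is not injective")
  }
  structure(list(x = x, pos = pos, edges = edges, pseudo = pseudo,
                 d_max = d_max, pixel_index = pixel_index,
                 slice_meta = slice_meta),
            class = "feature_graph")
}

compute_pseudo <- function(pos, edges, d_max) {
  if (!nrow(edges)) return(matrix(numeric(0), 0, 2))
  d <- pos[edges[, 2], , drop = FALSE] - pos[edges[, 1], , drop = FALSE]
  (d + d_max) / (2 * d_max)
}

#' @export
print.feature_graph <- function(x, ...) {
  cat("feature_graph: ", nrow(x$x), " nodes, ", nrow(x$edges),
      " directed edges, ", ncol(x$x), " channels\n", sep = "")
  invisible(x)
}

n_nodes <- function(graph) nrow(graph$x)

empty_graph_condition <- function(msg) {
  structure(class = c("gfcn_empty_graph", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

grid_offsets <- function(connectivity) {
  if (connectivity == 4L) {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else if (connectivity == 8L) {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1)[-5, ])
  } else stop("connectivity must be 4 or 8")
}

#' Convert one slice of a case volume to a feature graph
#'
#' Each retained pixel becomes a node carrying the five channel values; edges
#' join pixels adjacent under 4- or 8-connectivity.  Edge pseudo-coordinates
#' are the relative pixel displacements mapped from `[-1, +1]` to `[0, 1]`
#' per component.
#'
#' @param volume a preprocessed [case_volume()].
#' @param slice_index slice along the first axis.
#' @param connectivity 4 or 8 (default 8: diagonal directions give the
#'   spline kernels distinct orientations to weight).
#' @param support `"brain"` (default) keeps only pixels where the perfusion
#'   channel sum is nonzero; `"all"` keeps the full grid.
#' @return A [feature_graph()] with `pixel_index` and `slice_meta` set.
#'   Signals a condition of class `gfcn_empty_graph` if no pixel is
#'   retained, so callers can skip slices without brain support.
#' @export
slice_to_graph <- function(volume, slice_index, connectivity = 8L,
                           support = c("brain", "all")) {
  stopifnot(inherits(volume, "case_volume"))
  support <- match.arg(support)
  d <- dim(volume$channels)
  if (slice_index < 1L || slice_index > d[2])
    stop("slice_index out of range")
  h <- d[3]; w <- d[4]
  keep <- if (support == "brain") slice_support(volume, slice_index)
          else matrix(TRUE, h, w)
  n <- sum(keep)
  if (n == 0L)
    stop(empty_graph_condition(paste0("empty support in slice ",
                                      slice_index)))
  id <- matrix(0L, h, w)
  id[keep] <- seq_len(n)
  wh <- which(keep, arr.ind = TRUE)      # ordered by node id
  feats <- matrix(0, n, 5)
  for (c in 1:5) feats[, c] <- volume$channels[c, slice_index, , ][keep]
  offs <- grid_offsets(as.integer(connectivity))
  src <- integer(0); dst <- integer(0)
  pr <- integer(0); pc <- integer(0)
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1]; dc <- offs[k, 2]
    r2 <- wh[, 1] + dr; c2 <- wh[, 2] + dc
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    j <- integer(length(ok))
    j[ok] <- id[cbind(r2[ok], c2[ok])]
    ok <- ok & j > 0L
    src <- c(src, id[wh[ok, , drop = FALSE]])
    dst <- c(dst, j[ok])
    pr <- c(pr, rep.int(as.integer(dr), sum(ok)))
    pc <- c(pc, rep.int(as.integer(dc), sum(ok)))
  }
  pseudo <- cbind((pr + 1) / 2, (pc + 1) / 2)
  feature_graph(feats, pos = cbind(wh[, 1] - 1, wh[, 2] - 1),
                edges = cbind(src, dst), pseudo = pseudo, d_max = 1,
                pixel_index = wh,
                slice_meta = list(case_id = volume$case_id,
                                  slice_index = slice_index,
                                  shape = c(h, w)),
                check = FALSE)
}

#' Write per-node values back onto the pixel grid
#'
#' Inverse of [slice_to_graph()] for one value per node: builds a
#' `(height, width)` matrix with `node_values` at the nodes' pixels and 0
#' at unsupported pixels.
#'
#' @param graph a [feature_graph()] built by [slice_to_graph()].
#' @param node_values numeric vector, one value per node.
#' @return A numeric matrix shaped like the source slice.
#' @export
graph_to_slice <- function(graph, node_values) {
  stopifnot(inherits(graph, "feature_graph"))
  if (is.null(graph$pixel_index) || is.null(graph$slice_meta))
    stop("graph does not carry a pixel mapping")
  if (length(node_values) != n_nodes(graph))
    stop("node_values length ", length(node_values),
         " does not match node count ", n_nodes(graph))
  out <- matrix(0, graph$slice_meta$shape[1], graph$slice_meta$shape[2])
  out[graph$pixel_index] <- node_values
  out
}
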