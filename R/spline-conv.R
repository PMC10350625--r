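#' B-spline kernel configuration
#'
#' Hyperparameters of the spline-kernel graph convolution: the kernel is a
#' grid of `k1 x k2` trainable control points over the pseudo-coordinate
#' square `[0,1]^2`, interpolated by open (non-periodic) uniform B-splines
#' of degree `m`.  Only `(m+1)^2` control points are active per edge, so the
#' kernel weight varies smoothly with edge direction.
#'
#' @param in_channels,out_channels positive integers.
#' @param kernel_size integer 2-vector `(k1, k2)` of control points per
#'   pseudo-coordinate dimension; each component must be `>= degree + 1`.
#' @param degree B-spline degree, 1 (linear), 2 or 3.
#' @param root_weight add a separate linear map on the center node.
#' @param bias add a bias vector.
#' @return An object of class `spline_kernel_config`.
#' @export
spline_kernel_config <- function(in_channels, out_channels,
                                 kernel_size = c(5L, 5L), degree = 1L,
                                 root_weight = TRUE, bias = TRUE) {
  kernel_size <- as.integer(rep(kernel_size, length.out = 2))
  degree <- as.integer(degree)
  if (!degree %in% 1:3) stop("degree must be 1, 2 or 3")
  if (any(kernel_size < degree + 1L))
    stop("kernel_size components must be >= degree + 1")
  if (in_channels < 1L || out_channels < 1L)
    stop("channel counts must be positive")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel_size = kernel_size, degree = degree,
                 root_weight = isTRUE(root_weight), bias = isTRUE(bias)),
            class = "spline_kernel_config")
}

# Cardinal B-spline basis values at offset t in [0,1]: (m+1) columns.
bspline_cardinal <- function(t, degree) {
  if (degree == 1L) {
    cbind(1 - t, t)
  } else if (degree == 2L) {
    cbind((1 - t)^2 / 2, -t^2 + t + 0.5, t^2 / 2)
  } else {
    cbind((1 - t)^3 / 6, (3 * t^3 - 6 * t^2 + 4) / 6,
          (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6, t^3 / 6)
  }
}

# One pseudo-coordinate dimension: values (E x (m+1)) and 0-based control
# indices of the first active control point.
bspline_dim <- function(u, k, degree) {
  v <- u * (k - degree)
  i <- pmin(floor(v), k - degree - 1)
  list(values = bspline_cardinal(v - i, degree), first = as.integer(i))
}

#' Evaluate the product B-spline basis over edge pseudo-coordinates
#'
#' For each edge returns the `(m+1)^2` nonzero products of the per-dimension
#' open B-spline basis values, together with the 1-based flat indices of the
#' corresponding control points (dimension 1 fastest).  The values of each
#' row are nonnegative and sum to 1 (partition of unity).
#'
#' @param pseudo numeric `E x 2` matrix with components in `[0,1]`.
#' @param config a [spline_kernel_config()].
#' @param clamp `"warn"` (default) clamps out-of-range components with a
#'   warning; `"error"` fails instead.
#' @return List with `values` (`E x (m+1)^2`) and `index`
#'   (`E x (m+1)^2`, integer, in `1..k1*k2`).
#' @export
spline_basis <- function(pseudo, config, clamp = c("warn", "error")) {
  clamp <- match.arg(clamp)
  pseudo <- as.matrix(pseudo)
  if (nrow(pseudo) && (min(pseudo) < 0 || max(pseudo) > 1)) {
    if (clamp == "error") stop("pseudo-coordinate outside [0,1]")
    excess <- max(0 - min(pseudo), max(pseudo) - 1)
    if (excess > 1e-9)
      warning(sprintf("clamping pseudo-coordinates to [0,1] (excess %.3g)",
                      excess))
    pseudo <- pmin(pmax(pseudo, 0), 1)
  }
  m <- config$degree
  k <- config$kernel_size
  d1 <- bspline_dim(pseudo[, 1], k[1], m)
  d2 <- bspline_dim(pseudo[, 2], k[2], m)
  p <- m + 1L
  e <- nrow(pseudo)
  values <- matrix(0, e, p * p)
  index <- matrix(0L, e, p * p)
  for (b in seq_len(p)) {
    for (a in seq_len(p)) {
      col <- (b - 1L) * p + a
      values[, col] <- d1$values[, a] * d2$values[, b]
      index[, col] <- (d1$first + a - 1L) + (d2$first + b - 1L) * k[1] + 1L
    }
  }
  list(values = values, index = index)
}

#' Initialize spline convolution parameters
#'
#' Control-point weights and the optional root/bias terms, Glorot-uniform
#' initialized (fan-in counts every active control point).
#'
#' @param config a [spline_kernel_config()].
#' @return List with `weight` (array `(k1*k2, in, out)`), `root`
#'   (`in x out` or `NULL`), `bias` (length `out` or `NULL`).
#' @export
spline_conv_params <- function(config) {
  kk <- prod(config$kernel_size)
  ci <- config$in_channels; co <- config$out_channels
  fan_in <- ci * (config$degree + 1)^2
  lim <- sqrt(6 / (fan_in + co))
  weight <- array(stats::runif(kk * ci * co, -lim, lim), c(kk, ci, co))
  root <- NULL
  if (config$root_weight) {
    lim_r <- sqrt(6 / (ci + co))
    root <- matrix(stats::runif(ci * co, -lim_r, lim_r), ci, co)
  }
  bias <- if (config$bias) numeric(co) else NULL
  list(weight = weight, root = root, bias = bias)
}

# ---- edge plan: precomputed gather/scatter structure for one topology ----
#
# Expands each edge into (m+1)^2 rows carrying the basis value and the flat
# control index, so a convolution becomes one dense matmul, one gather and
# one rowsum.  `finalize = FALSE` keeps only concatenation-ready vectors for
# disjoint-union batching.
make_conv_plan <- function(edges, pseudo, n_nodes, config, finalize = TRUE) {
  p2 <- (config$degree + 1L)^2
  if (nrow(edges)) {
    sb <- spline_basis(pseudo, config)
    tkeep <- which(sb$values != 0)  # drop zero-weight products
    src <- rep(edges[, 1], p2)[tkeep]
    dst <- rep(edges[, 2], p2)[tkeep]
    q <- as.integer(sb$index)[tkeep]
    bval <- as.numeric(sb$values)[tkeep]
    deg <- tabulate(edges[, 2], n_nodes)
  } else {
    src <- dst <- q <- integer(0)
    bval <- numeric(0)
    deg <- integer(n_nodes)
  }
  plan <- list(N = n_nodes, K = prod(config$kernel_size), config = config,
               src = src, dst = dst, q = q, bval = bval, deg = deg)
  if (finalize) plan <- finalize_conv_plan(plan)
  plan
}

finalize_conv_plan <- function(plan) {
  idx <- (plan$q - 1L) * plan$N + plan$src
  inv_deg <- 1 / pmax(plan$deg, 1L)
  # One sparse matrix per topology turns the convolution into a single
  # sparse-dense product: out = M %*% Hstack, with the mean aggregation
  # folded into the entries.  Duplicate (dst, idx) pairs sum as required.
  plan$M <- Matrix::sparseMatrix(i = plan$dst, j = idx,
                                 x = plan$bval * inv_deg[plan$dst],
                                 dims = c(plan$N, plan$N * plan$K))
  plan
}

# Disjoint union of per-graph plans (graph batching).
union_conv_plans <- function(plans) {
  ns <- vapply(plans, `[[`, integer(1), "N")
  off <- cumsum(c(0L, ns[-length(ns)]))
  plan <- list(N = sum(ns), K = plans[[1]]$K, config = plans[[1]]$config,
               src = unlist(lapply(seq_along(plans),
                                   function(i) plans[[i]]$src + off[i])),
               dst = unlist(lapply(seq_along(plans),
                                   function(i) plans[[i]]$dst + off[i])),
               q = unlist(lapply(plans, `[[`, "q")),
               bval = unlist(lapply(plans, `[[`, "bval")),
               deg = unlist(lapply(plans, `[[`, "deg")))
  finalize_conv_plan(plan)
}

flatten_weight <- function(weight) {
  d <- dim(weight)  # (K, Cin, Cout)
  matrix(aperm(weight, c(2, 1, 3)), d[2], d[1] * d[3])
}

unflatten_weight <- function(wmat, k, ci, co) {
  aperm(array(wmat, c(ci, k, co)), c(2, 1, 3))
}

# rowsum scattering into a fixed number of rows.
rowsum_into <- function(values, group, n_rows) {
  out <- matrix(0, n_rows, ncol(values))
  if (nrow(values)) {
    rs <- rowsum(values, group)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

conv_forward_plan <- function(plan, x, params, wmat = NULL) {
  n <- plan$N
  co <- dim(params$weight)[3]
  if (length(plan$src)) {
    if (is.null(wmat)) wmat <- flatten_weight(params$weight)
    xw <- x %*% wmat                            # N x (K*Cout), q fastest
    dim(xw) <- c(n * plan$K, co)                # row (q-1)*N + i
    out <- as.matrix(plan$M %*% xw)
  } else {
    out <- matrix(0, n, co)
  }
  if (!is.null(params$root)) out <- out + x %*% params$root
  if (!is.null(params$bias))
    out <- out + rep(params$bias, each = n)
  out
}

conv_backward_plan <- function(plan, x, params, g, wmat = NULL) {
  n <- plan$N
  k <- plan$K
  ci <- dim(params$weight)[2]; co <- dim(params$weight)[3]
  if (length(plan$src)) {
    dxw <- as.matrix(Matrix::crossprod(plan$M, g))          # (N*K) x Cout
    dim(dxw) <- c(n, k * co)
    if (is.null(wmat)) wmat <- flatten_weight(params$weight)
    dweight <- unflatten_weight(crossprod(x, dxw), k, ci, co)
    dx <- dxw %*% t(wmat)
  } else {
    dweight <- array(0, dim(params$weight))
    dx <- matrix(0, nrow(x), ci)
  }
  droot <- NULL
  if (!is.null(params$root)) {
    droot <- crossprod(x, g)
    dx <- dx + g %*% t(params$root)
  }
  dbias <- if (!is.null(params$bias)) colSums(g) else NULL
  list(dx = dx, dweight = dweight, droot = droot, dbias = dbias)
}

#' Spline-kernel graph convolution (forward)
#'
#' Computes, for each node `i`,
#' `out_i = (1/|N(i)|) * sum_{j in N(i)} [sum_p B_p(u_ji) W_p]' x_j
#'  + R' x_i + b`,
#' where `N(i)` are the sources of edges into `i`, `u_ji` is the edge
#' pseudo-coordinate and `B_p` the product B-spline basis.  Aggregation is
#' degree-normalized (mean); nodes without incoming edges receive only the
#' root and bias terms.
#'
#' @param graph a [feature_graph()] whose features have
#'   `config$in_channels` columns.
#' @param params parameters as returned by [spline_conv_params()].
#' @param config the [spline_kernel_config()].
#' @return Numeric `N x out_channels` matrix.
#' @export
spline_conv_forward <- function(graph, params, config) {
  stopifnot(inherits(graph, "feature_graph"))
  if (n_nodes(graph) == 0L) stop("empty graph")
  if (ncol(graph$x) != config$in_channels)
    stop("feature width ", ncol(graph$x), " != in_channels ",
         config$in_channels)
  plan <- make_conv_plan(graph$edges, graph$pseudo, n_nodes(graph), config)
  conv_forward_plan(plan, graph$x, params)
}
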