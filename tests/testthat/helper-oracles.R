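# Fixture builders and independent brute-force oracles shared by the tests.

# A free grid graph (not tied to a volume): h x w pixels, all retained.
grid_graph <- function(h, w, connectivity = 8L, features = NULL,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(features)) features <- matrix(rnorm(h * w * 3), h * w, 3)
  vol <- case_volume(array(1, c(5, 1, h, w)), array(0, c(1, h, w)))
  g <- slice_to_graph(vol, 1, connectivity, "all")
  feature_graph(features, g$pos, g$edges, pseudo = g$pseudo,
                d_max = g$d_max, pixel_index = g$pixel_index,
                slice_meta = g$slice_meta, check = FALSE)
}

# Random symmetric graph with random positions (edge prob p).
random_graph <- function(n, p = 0.4, n_features = 3, seed = 1) {
  set.seed(seed)
  pos <- matrix(runif(n * 2, 0, 10), n, 2)
  src <- integer(0); dst <- integer(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p) { src <- c(src, i, j); dst <- c(dst, j, i) }
  }
  d_max <- if (length(src)) max(abs(pos[dst, ] - pos[src, ])) else 1
  feature_graph(matrix(rnorm(n * n_features), n, n_features), pos,
                cbind(src, dst), d_max = max(d_max, 1e-9), check = FALSE)
}

# Direct per-node, per-edge evaluation of the spline convolution.
brute_spline_conv <- function(graph, params, config) {
  n <- nrow(graph$x)
  out <- matrix(0, n, config$out_channels)
  sb <- spline_basis(graph$pseudo, config)
  for (i in seq_len(n)) {
    eids <- which(graph$edges[, 2] == i)
    if (length(eids)) {
      acc <- numeric(config$out_channels)
      for (e in eids) {
        j <- graph$edges[e, 1]
        w <- matrix(0, config$in_channels, config$out_channels)
        for (p in seq_len(ncol(sb$values)))
          w <- w + sb$values[e, p] * params$weight[sb$index[e, p], , ]
        acc <- acc + as.numeric(graph$x[j, ] %*% w)
      }
      out[i, ] <- acc / length(eids)
    }
    if (!is.null(params$root))
      out[i, ] <- out[i, ] + as.numeric(graph$x[i, ] %*% params$root)
  }
  if (!is.null(params$bias)) out <- sweep(out, 2, params$bias, "+")
  out
}

# O(|A| * |B|) double-loop Hausdorff oracle on binary masks.
brute_hausdorff <- function(a, b, spacing = 1) {
  dims <- dim(as.array(a))
  spacing <- rep(spacing, length.out = length(dims))
  ca <- which(as.array(a) == 1, arr.ind = TRUE)
  cb <- which(as.array(b) == 1, arr.ind = TRUE)
  if (is.vector(ca)) ca <- matrix(ca, ncol = 1)
  if (is.vector(cb)) cb <- matrix(cb, ncol = 1)
  if (nrow(ca) == 0 && nrow(cb) == 0) return(0)
  if (nrow(ca) == 0 || nrow(cb) == 0)
    return(sqrt(sum((dims * spacing)^2)))
  ca <- sweep(ca, 2, spacing, "*"); cb <- sweep(cb, 2, spacing, "*")
  dmin_a <- apply(ca, 1, function(p)
    min(sqrt(colSums((t(cb) - p)^2))))
  dmin_b <- apply(cb, 1, function(p)
    min(sqrt(colSums((t(ca) - p)^2))))
  max(max(dmin_a), max(dmin_b))
}

# Permute the nodes of a feature graph: node i becomes q[i].
permute_graph <- function(graph, q) {
  inv <- integer(length(q)); inv[q] <- seq_along(q)
  px <- graph$x[inv, , drop = FALSE]
  ppos <- graph$pos[inv, , drop = FALSE]
  pedges <- cbind(q[graph$edges[, 1]], q[graph$edges[, 2]])
  ppix <- if (!is.null(graph$pixel_index))
    graph$pixel_index[inv, , drop = FALSE]
  feature_graph(px, ppos, pedges,
                pseudo = compute_pseudo(ppos, pedges, graph$d_max),
                d_max = graph$d_max, pixel_index = ppix,
                slice_meta = graph$slice_meta, check = FALSE)
}
compute_pseudo <- gfcn:::compute_pseudo

# A small deterministic phantom dataset shared by training tests.
tiny_phantom_cases <- function(n_cases = 2, shape = c(2L, 16L, 16L),
                               seed = 11) {
  spec <- phantom_spec(shape = shape, n_cases = n_cases, seed = seed)
  cases <- lapply(seq_len(n_cases), function(i) make_case(spec, i))
  names(cases) <- vapply(cases, `[[`, character(1), "case_id")
  cases
}
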