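#' Pooling record
#'
#' The per-level coarsening trace that makes pooling invertible in topology:
#' the fine-to-coarse cluster assignment, a snapshot of the fine features the
#' pool aggregated, and fine/coarse node positions.  Consumed by the
#' unpooling operators.
#'
#' @param cluster_of integer vector, fine node -> coarse node (1-based);
#'   `NA` marks nodes dropped by Top-k selection.
#' @param stored_fine_features numeric `N_fine x C` snapshot taken at
#'   pooling time.
#' @param fine_positions,coarse_positions numeric position matrices.
#' @param level integer coarsening level.
#' @param check validate totality/surjectivity (disabled on trusted
#'   internal construction).
#' @return An object of class `pool_record`.
#' @export
pool_record <- function(cluster_of, stored_fine_features, fine_positions,
                        coarse_positions, level = 1L, check = TRUE) {
  n_coarse <- nrow(coarse_positions)
  cl <- as.integer(cluster_of)
  if (check) {
    seen <- unique(cl[!is.na(cl)])
    if (length(seen) && (min(seen) < 1L || max(seen) > n_coarse))
      stop("cluster assignment out of range")
    if (!setequal(seen, seq_len(n_coarse)))
      stop("cluster assignment is not surjective onto the coarse nodes")
  }
  structure(list(cluster_of = cl,
                 stored_fine_features = stored_fine_features,
                 fine_positions = fine_positions,
                 coarse_positions = coarse_positions,
                 level = as.integer(level)),
            class = "pool_record")
}

# Seeded deterministic key per node, a function of position only, so that
# visiting orders commute with node relabeling while staying reproducible.
position_keys <- function(pos, seed) {
  a <- 12.9898 + (seed %% 97) * 0.173
  b <- 78.233 + (seed %% 89) * 0.311
  v <- sin(a * (pos[, 1] + 1.7) + b * (pos[, 2] + 3.1) + seed * 0.0001)
  v * 43758.5453 - floor(v * 43758.5453)
}

adjacency_list <- function(edges, n) {
  adj <- vector("list", n)
  if (nrow(edges)) {
    o <- order(edges[, 1])
    adj_split <- split(edges[o, 2], edges[o, 1])
    adj[as.integer(names(adj_split))] <- adj_split
  }
  adj
}

# Greedy normalized-cut matching: visit unmatched nodes in the seeded
# position-key order; each node matches the unmatched neighbor maximizing
# w * (1/d_i + 1/d_j) with uniform edge weight w = 1, else stays singleton.
graclus_clusters <- function(graph, seed = 1L) {
  n <- n_nodes(graph)
  adj <- adjacency_list(graph$edges, n)
  deg <- lengths(adj)
  keys <- position_keys(graph$pos, seed)
  visit <- order(keys)
  cl <- integer(n)
  next_id <- 0L
  for (i in visit) {
    if (cl[i] > 0L) next
    nb <- adj[[i]]
    nb <- nb[cl[nb] == 0L]
    next_id <- next_id + 1L
    cl[i] <- next_id
    if (length(nb)) {
      score <- 1 / deg[i] + 1 / deg[nb]
      best <- nb[score == max(score)]
      j <- best[which.min(keys[best])]   # tie-break by key: equivariant
      cl[j] <- next_id
    }
  }
  cl
}

# Per-channel max over clusters; returns values and argmax fine rows.
pool_max <- function(x, cl, n_coarse) {
  n <- nrow(x); c <- ncol(x)
  live <- which(!is.na(cl))
  vals <- matrix(-Inf, n_coarse, c)
  amax <- matrix(NA_integer_, n_coarse, c)
  for (j in seq_len(c)) {
    o <- live[order(cl[live], x[live, j])]
    grp <- cl[o]
    last <- which(c(grp[-1] != grp[-length(grp)], TRUE))
    rows <- o[last]
    vals[grp[last], j] <- x[rows, j]
    amax[grp[last], j] <- rows
  }
  list(values = vals, argmax = amax)
}

pool_max_backward <- function(g_coarse, argmax, n_fine) {
  dx <- matrix(0, n_fine, ncol(g_coarse))
  for (j in seq_len(ncol(g_coarse))) {
    ok <- !is.na(argmax[, j])
    dx[cbind(argmax[ok, j], j)] <- dx[cbind(argmax[ok, j], j)] +
      g_coarse[ok, j]
  }
  dx
}

# Coarse topology: centroid positions, deduplicated inter-cluster edges,
# pseudo-coordinates renormalized by this level's own max displacement.
coarse_topology <- function(pos, edges, cl, n_coarse,
                            coarse_pos = NULL) {
  if (is.null(coarse_pos)) {
    coarse_pos <- cbind(
      as.numeric(rowsum_into(pos[, 1, drop = FALSE], cl, n_coarse)),
      as.numeric(rowsum_into(pos[, 2, drop = FALSE], cl, n_coarse)))
    counts <- tabulate(cl, n_coarse)
    coarse_pos <- coarse_pos / counts
  }
  if (nrow(edges)) {
    a <- cl[edges[, 1]]; b <- cl[edges[, 2]]
    ok <- !is.na(a) & !is.na(b) & a != b
    a <- a[ok]; b <- b[ok]
    key <- (a - 1) * n_coarse + b          # integer dedup, no unique.matrix
    kk <- !duplicated(key)
    ce <- cbind(a[kk], b[kk])
  } else {
    ce <- matrix(integer(0), 0, 2)
  }
  d_max <- 1
  if (nrow(ce)) {
    disp <- coarse_pos[ce[, 2], , drop = FALSE] -
      coarse_pos[ce[, 1], , drop = FALSE]
    d_max <- max(abs(disp), 1e-12)
  }
  list(pos = coarse_pos, edges = ce, d_max = d_max)
}

#' Graclus pooling
#'
#' Coarsens the graph by seeded greedy normalized-cut matching (clusters of
#' size 1 or 2), aggregates member features with the per-channel max
#' operator, places each coarse node at its members' centroid, and maps fine
#' edges to deduplicated inter-cluster coarse edges with pseudo-coordinates
#' renormalized by the level's maximum displacement.
#'
#' @param graph a nonempty [feature_graph()].
#' @param seed integer; fixes the matching deterministically.
#' @param level stored in the record.
#' @return List with `coarse` ([feature_graph()]) and `record`
#'   ([pool_record()]).
#' @export
graclus_pool <- function(graph, seed = 1L, level = 1L) {
  if (n_nodes(graph) == 0L) stop("empty graph")
  cl <- graclus_clusters(graph, seed)
  n_coarse <- max(cl)
  pm <- pool_max(graph$x, cl, n_coarse)
  topo <- coarse_topology(graph$pos, graph$edges, cl, n_coarse)
  coarse <- feature_graph(pm$values, topo$pos, topo$edges,
                          d_max = topo$d_max, check = FALSE)
  rec <- pool_record(cl, graph$x, graph$pos, topo$pos, level)
  list(coarse = coarse, record = rec)
}

#' Top-k pooling
#'
#' Scores nodes by projection onto a trainable direction
#' (`s_i = x_i' p / ||p||`), keeps the `ceiling(ratio * N)` highest-scoring
#' nodes (ties broken by lower node index), gates the retained features by
#' `tanh(s_i)`, and induces the subgraph on the kept nodes.  Dropped nodes
#' map to `NA` in the record and are recovered by kNN unpooling.
#'
#' @param graph a nonempty [feature_graph()].
#' @param projection numeric length-C vector with nonzero norm.
#' @param ratio fraction of nodes to keep, in `(0, 1]`.
#' @param level stored in the record.
#' @return List with `coarse`, `record`, and `keep` (the kept fine indices
#'   in score order).
#' @export
topk_pool <- function(graph, projection, ratio = 0.5, level = 1L) {
  if (n_nodes(graph) == 0L) stop("empty graph")
  pn <- sqrt(sum(projection^2))
  if (pn == 0) stop("projection vector must be nonzero")
  n <- n_nodes(graph)
  s <- as.numeric(graph$x %*% (projection / pn))
  k <- ceiling(ratio * n)
  keep <- order(-s, seq_len(n))[seq_len(k)]
  cl <- rep(NA_integer_, n)
  cl[keep] <- seq_len(k)
  xk <- graph$x[keep, , drop = FALSE] * tanh(s[keep])
  if (nrow(graph$edges)) {
    map <- cl[graph$edges]
    dim(map) <- dim(graph$edges)
    ok <- !is.na(map[, 1]) & !is.na(map[, 2])
    ce <- map[ok, , drop = FALSE]
  } else ce <- matrix(integer(0), 0, 2)
  cpos <- graph$pos[keep, , drop = FALSE]
  d_max <- 1
  if (nrow(ce)) {
    disp <- cpos[ce[, 2], , drop = FALSE] - cpos[ce[, 1], , drop = FALSE]
    d_max <- max(abs(disp), 1e-12)
  }
  coarse <- feature_graph(xk, cpos, ce, d_max = d_max, check = FALSE)
  rec <- pool_record(cl, graph$x, graph$pos, cpos, level)
  list(coarse = coarse, record = rec, keep = keep, score = s)
}

# Gradient of the Top-k gate wrt kept-node output g (k x C):
# y = x_keep * tanh(s_keep), s = X p_hat.
topk_backward <- function(graph, keep, score, projection, g) {
  pn <- sqrt(sum(projection^2))
  phat <- projection / pn
  xk <- graph$x[keep, , drop = FALSE]
  t <- tanh(score[keep])
  dx <- matrix(0, n_nodes(graph), ncol(graph$x))
  inner <- rowSums(g * xk)              # dL/d t_i per kept node
  ds <- inner * (1 - t^2)
  dx[keep, ] <- g * t + outer(ds, phat)
  dphat <- colSums(xk * ds)
  dproj <- (dphat - phat * sum(phat * dphat)) / pn
  list(dx = dx, dprojection = dproj)
}

#' Farthest-point-sampling radius pooling
#'
#' Selects `ceiling(ratio * N)` centers by farthest-point sampling on node
#' positions (the first center is node 1; each subsequent center maximizes
#' its distance to the chosen set), assigns every node to its nearest
#' center (nodes beyond `radius` still join their nearest center, so the
#' assignment is total), aggregates with per-channel max, and keeps the
#' centers' positions for the coarse nodes.
#'
#' @param graph a nonempty [feature_graph()].
#' @param ratio fraction of nodes to keep as centers, in `(0, 1]`.
#' @param radius nominal assignment radius in pixels (> 0).
#' @param level stored in the record.
#' @return List with `coarse`, `record`, and `centers` (fine indices).
#' @export
fps_radius_pool <- function(graph, ratio = 0.5, radius = 2, level = 1L) {
  if (n_nodes(graph) == 0L) stop("empty graph")
  if (radius <= 0) stop("radius must be positive")
  n <- n_nodes(graph)
  k <- ceiling(ratio * n)
  pos <- graph$pos
  centers <- integer(k)
  centers[1] <- 1L
  d2 <- rowSums((pos - matrix(pos[1, ], n, 2, byrow = TRUE))^2)
  if (k > 1) {
    for (i in 2:k) {
      centers[i] <- which.max(d2)
      nd <- rowSums((pos - matrix(pos[centers[i], ], n, 2,
                                  byrow = TRUE))^2)
      d2 <- pmin(d2, nd)
    }
  }
  cpos <- pos[centers, , drop = FALSE]
  # nearest center per node
  cl <- integer(n)
  best <- rep(Inf, n)
  for (i in seq_len(k)) {
    nd <- rowSums((pos - matrix(cpos[i, ], n, 2, byrow = TRUE))^2)
    upd <- nd < best
    best[upd] <- nd[upd]
    cl[upd] <- i
  }
  pm <- pool_max(graph$x, cl, k)
  topo <- coarse_topology(pos, graph$edges, cl, k, coarse_pos = cpos)
  coarse <- feature_graph(pm$values, cpos, topo$edges, d_max = topo$d_max,
                          check = FALSE)
  rec <- pool_record(cl, graph$x, pos, cpos, level)
  list(coarse = coarse, record = rec, centers = centers)
}
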