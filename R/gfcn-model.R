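#' Model configuration for the graph FCN
#'
#' Assembles the hyperparameters of the encoder-decoder graph network.
#' The encoder runs `depth` convolution blocks, each followed by a pooling
#' step (topologies `V0 -> V1 -> ... -> V_depth`); each block applies two
#' spline convolutions with batch normalization and ELU activation and
#' doubles the feature width.  The decoder converts selected feature maps
#' to 1-channel score maps, fuses them additively FCN-style, and unpools
#' back to the input topology:
#'
#' * `"32s"`: the top score map is unpooled all the way to `V0` without
#'   skip connections.
#' * `"16s"`: the top score map is unpooled to `V2`, the `V2` score map is
#'   added, and the sum is unpooled to `V0`.
#' * `"8s"`: the top score map is unpooled one level, fused with the score
#'   of `V_{depth-1}`, unpooled again, fused with the score of
#'   `V_{depth-2}`, then unpooled to `V0`.
#'
#' A sigmoid on the `V0` score yields per-node lesion probabilities.
#'
#' @param variant `"8s"`, `"16s"` or `"32s"`.
#' @param depth number of pooling levels (default 4).  `"16s"` requires
#'   `depth >= 2`, `"8s"` requires `depth >= 4`.
#' @param base_channels width of the first block (default 32); block `b`
#'   outputs `base_channels * 2^(b-1)` channels.
#' @param bn_placement `"pre"` (conv -> BN -> activation, default) or
#'   `"post"` (conv -> activation -> BN).
#' @param pooling `"graclus"`, `"topk"` or `"none"`.
#' @param unpooling `"isotropic"`, `"proportional"` or `"knn"`; defaults to
#'   the partner of the pooling choice (graclus pairs with isotropic or
#'   proportional, topk with knn, none forbids unpooling).
#' @param kernel_size,degree spline kernel hyperparameters (defaults 5x5
#'   control points, degree 1).
#' @param topk_ratio per-level keep ratio for Top-k pooling.
#' @param knn_k neighbor count for kNN unpooling.
#' @param epsilon guard constant for divisions.
#' @param in_channels input feature width (5 modality channels).
#' @param connectivity,support slice-graph construction options passed to
#'   [slice_to_graph()].
#' @param seed integer seed fixing initialization and the Graclus matching.
#' @return An object of class `gfcn_config`.
#' @export
gfcn_config <- function(variant = c("8s", "16s", "32s"), depth = 4L,
                        base_channels = 32L,
                        bn_placement = c("pre", "post"),
                        pooling = c("graclus", "topk", "none"),
                        unpooling = NULL, kernel_size = c(5L, 5L),
                        degree = 1L, topk_ratio = 0.5, knn_k = 3L,
                        epsilon = 1e-8, in_channels = 5L,
                        connectivity = 8L, support = "brain", seed = 1L) {
  variant <- match.arg(variant)
  bn_placement <- match.arg(bn_placement)
  pooling <- match.arg(pooling)
  depth <- as.integer(depth)
  if (variant == "16s" && depth < 2L) stop("variant 16s requires depth >= 2")
  if (variant == "8s" && depth < 4L) stop("variant 8s requires depth >= 4")
  if (depth < 1L) stop("depth must be >= 1")
  if (is.null(unpooling))
    unpooling <- switch(pooling, graclus = "isotropic", topk = "knn",
                        none = "none")
  if (pooling == "none" && unpooling != "none")
    stop("pooling 'none' forbids unpooling")
  if (pooling == "graclus" &&
      !unpooling %in% c("isotropic", "proportional"))
    stop("graclus pooling pairs with isotropic or proportional unpooling")
  if (pooling == "topk" && unpooling != "knn")
    stop("topk pooling pairs with knn unpooling")
  structure(list(variant = variant, depth = depth,
                 base_channels = as.integer(base_channels),
                 bn_placement = bn_placement, pooling = pooling,
                 unpooling = unpooling,
                 kernel_size = as.integer(rep(kernel_size,
                                              length.out = 2)),
                 degree = as.integer(degree), topk_ratio = topk_ratio,
                 knn_k = as.integer(knn_k), epsilon = epsilon,
                 in_channels = as.integer(in_channels),
                 connectivity = as.integer(connectivity),
                 support = support, seed = as.integer(seed)),
            class = "gfcn_config")
}

block_widths <- function(config) {
  out <- config$base_channels * 2L^(seq_len(config$depth) - 1L)
  list(inp = c(config$in_channels, out[-config$depth]), out = out)
}

# Levels tapped by the decoder score layers, besides the top level.
skip_levels <- function(config) {
  switch(config$variant,
         "32s" = integer(0),
         "16s" = 2L,
         "8s" = c(config$depth - 1L, config$depth - 2L))
}

block_spline_configs <- function(config) {
  bw <- block_widths(config)
  lapply(seq_len(config$depth), function(b) {
    list(conv1 = spline_kernel_config(bw$inp[b], bw$out[b],
                                      config$kernel_size, config$degree),
         conv2 = spline_kernel_config(bw$out[b], bw$out[b],
                                      config$kernel_size, config$degree))
  })
}

#' Initialize a graph FCN model
#'
#' Seeded parameter initialization: spline convolution weights
#' (Glorot-uniform), batch-norm scale/shift (1/0), 1-channel score layers,
#' and Top-k projections when that pooling is selected.  Batch-norm running
#' statistics start at mean 0 / variance 1.
#'
#' @param config a [gfcn_config()].
#' @return An object of class `gfcn_model`: list with `config`, `params`
#'   and `state`.
#' @export
gfcn_init <- function(config) {
  stopifnot(inherits(config, "gfcn_config"))
  set.seed(config$seed)
  bw <- block_widths(config)
  scfg <- block_spline_configs(config)
  blocks <- lapply(seq_len(config$depth), function(b) {
    list(conv1 = spline_conv_params(scfg[[b]]$conv1),
         bn1 = list(gamma = rep(1, bw$out[b]), beta = rep(0, bw$out[b])),
         conv2 = spline_conv_params(scfg[[b]]$conv2),
         bn2 = list(gamma = rep(1, bw$out[b]), beta = rep(0, bw$out[b])))
  })
  score_init <- function(ci) {
    lim <- sqrt(6 / (ci + 1))
    list(w = matrix(stats::runif(ci, -lim, lim), ci, 1), b = 0)
  }
  scores <- list(top = score_init(bw$out[config$depth]))
  sk <- skip_levels(config)
  for (l in sk) scores[[paste0("v", l)]] <- score_init(bw$out[l])
  params <- list(blocks = blocks, scores = scores)
  if (config$pooling == "topk")
    params$topk <- lapply(seq_len(config$depth), function(b)
      list(projection = stats::rnorm(bw$out[b]) / sqrt(bw$out[b])))
  state <- list(bn = lapply(seq_len(config$depth), function(b)
    list(bn1 = list(mean = rep(0, bw$out[b]), var = rep(1, bw$out[b])),
         bn2 = list(mean = rep(0, bw$out[b]), var = rep(1, bw$out[b])))))
  structure(list(config = config, params = params, state = state),
            class = "gfcn_model")
}

#' Number of trainable parameters
#'
#' @param model a `gfcn_model`.
#' @return Integer count of scalar trainable parameters.
#' @export
n_params <- function(model) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk)
    else if (is.numeric(x)) n <<- n + length(x)
    invisible(NULL)
  }
  walk(model$params)
  n
}

#' @export
print.gfcn_model <- function(x, ...) {
  cat("gfcn_model GFCN-", x$config$variant, ": depth ", x$config$depth,
      ", base ", x$config$base_channels, ", pooling ", x$config$pooling,
      "/", x$config$unpooling, ", ", n_params(x), " parameters\n",
      sep = "")
  invisible(x)
}

# ---- elementary layers ----------------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_forward <- function(x, p, run, train) {
  if (train) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc * xc)
    inv_std <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(xc, 2, inv_std, "*")
    run$mean <- (1 - BN_MOMENTUM) * run$mean + BN_MOMENTUM * mu
    run$var <- (1 - BN_MOMENTUM) * run$var + BN_MOMENTUM * v
  } else {
    inv_std <- 1 / sqrt(run$var + BN_EPS)
    xhat <- sweep(sweep(x, 2, run$mean), 2, inv_std, "*")
  }
  y <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  list(y = y, cache = list(xhat = xhat, inv_std = inv_std), run = run)
}

bn_backward <- function(cache, p, dy) {
  n <- nrow(dy)
  dxhat <- sweep(dy, 2, p$gamma, "*")
  sum_d <- colSums(dxhat)
  sum_dx <- colSums(dxhat * cache$xhat)
  dx <- sweep(dxhat, 2, sum_d / n) -
    sweep(cache$xhat, 2, sum_dx / n, "*")
  dx <- sweep(dx, 2, cache$inv_std, "*")
  list(dx = dx, dgamma = colSums(dy * cache$xhat), dbeta = colSums(dy))
}

elu_forward <- function(x) {
  neg <- x <= 0
  y <- x
  y[neg] <- expm1(x[neg])
  list(y = y, cache = list(neg = neg, y = y))
}

elu_backward <- function(cache, dy) {
  d <- dy
  d[cache$neg] <- dy[cache$neg] * (cache$y[cache$neg] + 1)
  d
}

# conv -> BN -> act ("pre") or conv -> act -> BN ("post")
stage_forward <- function(plan, x, conv_p, bn_p, bn_run, placement,
                          train) {
  wmat <- if (length(plan$src)) flatten_weight(conv_p$weight)
  z <- conv_forward_plan(plan, x, conv_p, wmat)
  if (placement == "pre") {
    bn <- bn_forward(z, bn_p, bn_run, train)
    act <- elu_forward(bn$y)
    y <- act$y
  } else {
    act <- elu_forward(z)
    bn <- bn_forward(act$y, bn_p, bn_run, train)
    y <- bn$y
  }
  list(y = y, run = bn$run,
       cache = list(x = x, bn = bn$cache, act = act$cache, wmat = wmat))
}

stage_backward <- function(plan, cache, conv_p, bn_p, placement, dy) {
  if (placement == "pre") {
    d1 <- elu_backward(cache$act, dy)
    bnb <- bn_backward(cache$bn, bn_p, d1)
    dz <- bnb$dx
  } else {
    bnb <- bn_backward(cache$bn, bn_p, dy)
    dz <- elu_backward(cache$act, bnb$dx)
  }
  cb <- conv_backward_plan(plan, cache$x, conv_p, dz, cache$wmat)
  list(dx = cb$dx,
       conv = list(weight = cb$dweight, root = cb$droot, bias = cb$dbias),
       bn = list(gamma = bnb$dgamma, beta = bnb$dbeta))
}

score_forward <- function(x, p) as.numeric(x %*% p$w + p$b)

score_backward <- function(x, p, ds) {
  ds <- matrix(ds, ncol = 1)
  list(dx = ds %*% t(p$w), dw = crossprod(x, ds), db = sum(ds))
}

# ---- input preparation and batching ---------------------------------------

#' Prepare a slice graph for the network
#'
#' Precomputes the static part of the computation: the spline gather plan at
#' every topology level and, for Graclus pooling, the full coarsening
#' hierarchy (cluster assignments, coarse positions, coarse edge plans).
#' The result can be reused across forward passes and training epochs, and
#' batched with [gfcn_batch()].  For Top-k pooling only the input level is
#' static (the selection depends on the features).
#'
#' @param config a [gfcn_config()].
#' @param graph a [feature_graph()] (typically from [slice_to_graph()]).
#' @param target optional binary per-node label vector (lesion mask).
#' @return An object of class `gfcn_input`.
#' @export
gfcn_prepare <- function(config, graph, target = NULL) {
  stopifnot(inherits(config, "gfcn_config"))
  if (n_nodes(graph) == 0L) stop("empty graph")
  scfg <- block_spline_configs(config)[[1]]$conv1  # kernel geometry only
  levels <- list(list(n = n_nodes(graph), pos = graph$pos,
                      plan = make_conv_plan(graph$edges, graph$pseudo,
                                            n_nodes(graph), scfg)))
  if (config$pooling == "graclus") {
    g <- feature_graph(matrix(0, n_nodes(graph), 1), graph$pos,
                       graph$edges, pseudo = graph$pseudo,
                       d_max = graph$d_max, check = FALSE)
    for (l in seq_len(config$depth)) {
      cl <- graclus_clusters(g, config$seed + l)
      nc <- max(cl)
      topo <- coarse_topology(g$pos, g$edges, cl, nc)
      levels[[l + 1L]] <- list(
        n = nc, pos = topo$pos, cl = cl,
        plan = make_conv_plan(topo$edges,
                              compute_pseudo(topo$pos, topo$edges,
                                             topo$d_max),
                              nc, scfg))
      g <- feature_graph(matrix(0, nc, 1), topo$pos, topo$edges,
                         d_max = topo$d_max, check = FALSE)
    }
  } else if (config$pooling == "none") {
    for (l in seq_len(config$depth)) levels[[l + 1L]] <- levels[[1L]]
  }
  structure(list(x = graph$x, y = target, levels = levels,
                 slice_meta = graph$slice_meta, graph = graph,
                 n = n_nodes(graph)),
            class = "gfcn_input")
}

#' Batch prepared inputs as one disjoint union
#'
#' Concatenates several prepared slice graphs into a single block-diagonal
#' graph per level, the standard graph-batching construction: features and
#' targets are stacked, node indices offset, and the spline gather plans
#' merged.  Batch normalization then normalizes over all nodes of the
#' batch.  Not available for Top-k pooling (whose hierarchy is dynamic).
#'
#' @param inputs list of `gfcn_input` objects from [gfcn_prepare()].
#' @return A `gfcn_input` covering the union.
#' @export
gfcn_batch <- function(inputs) {
  if (length(inputs) == 1L) return(inputs[[1L]])
  n_levels <- length(inputs[[1L]]$levels)
  levels <- vector("list", n_levels)
  for (l in seq_len(n_levels)) {
    ls <- lapply(inputs, function(p) p$levels[[l]])
    ns <- vapply(ls, `[[`, numeric(1), "n")
    lev <- list(n = sum(ns), pos = do.call(rbind, lapply(ls, `[[`, "pos")),
                plan = union_conv_plans(lapply(ls, `[[`, "plan")))
    if (!is.null(ls[[1L]]$cl)) {
      off <- cumsum(c(0L, ns[-length(ns)]))
      lev$cl <- unlist(lapply(seq_along(ls),
                              function(i) ls[[i]]$cl + off[i]))
    }
    levels[[l]] <- lev
  }
  ys <- lapply(inputs, `[[`, "y")
  structure(list(x = do.call(rbind, lapply(inputs, `[[`, "x")),
                 y = if (!any(vapply(ys, is.null, logical(1))))
                   unlist(ys),
                 levels = levels, slice_meta = NULL, graph = NULL,
                 n = sum(vapply(inputs, `[[`, numeric(1), "n"))),
            class = "gfcn_input")
}

# ---- forward / backward ---------------------------------------------------

# Rebuild a conv plan for an arbitrary edge set (Top-k dynamic levels).
plan_for_graph <- function(graph, config) {
  scfg <- spline_kernel_config(1L, 1L, config$kernel_size, config$degree)
  make_conv_plan(graph$edges, graph$pseudo, n_nodes(graph), scfg)
}

#' Run the network forward
#'
#' Executes encoder, pooling, score layers, skip fusion, unpooling and the
#' final sigmoid, returning the full forward trace needed for
#' backpropagation and for mapping probabilities back to pixels.
#'
#' @param model a `gfcn_model` from [gfcn_init()].
#' @param input a `gfcn_input` from [gfcn_prepare()]/[gfcn_batch()], or a
#'   [feature_graph()] (prepared on the fly).
#' @param train logical; `TRUE` uses batch statistics in batch norm (and
#'   updates the running statistics in the returned trace), `FALSE` uses
#'   the stored running statistics (deterministic evaluation mode).
#' @return An object of class `gfcn_trace` with elements `prob` (per-node
#'   probabilities on the input topology), `score0` (pre-sigmoid scores),
#'   `records` (one [pool_record()] per level, empty when pooling is
#'   `"none"`), `graphs_n` (node counts per level), `state` (updated batch
#'   norm state) and the caches used by `gfcn_backward()`.
#' @export
gfcn_forward <- function(model, input, train = FALSE) {
  stopifnot(inherits(model, "gfcn_model"))
  cfg <- model$config
  if (inherits(input, "feature_graph"))
    input <- gfcn_prepare(cfg, input)
  depth <- cfg$depth
  x <- input$x
  if (ncol(x) != cfg$in_channels)
    stop("input feature width ", ncol(x), " != in_channels ",
         cfg$in_channels)
  state <- model$state
  blocks <- model$params$blocks
  bcache <- vector("list", depth)
  pcache <- vector("list", depth)
  taps <- vector("list", depth)
  records <- list()
  graphs_n <- input$n
  # dynamic level bookkeeping for Top-k
  cur_pos <- input$levels[[1L]]$pos
  cur_graph <- input$graph
  for (b in seq_len(depth)) {
    plan <- if (cfg$pooling == "topk") {
      if (b == 1L) input$levels[[1L]]$plan
      else pcache[[b - 1L]]$next_plan
    } else if (cfg$pooling == "none") {
      input$levels[[1L]]$plan
    } else input$levels[[b]]$plan
    s1 <- stage_forward(plan, x, blocks[[b]]$conv1, blocks[[b]]$bn1,
                        state$bn[[b]]$bn1, cfg$bn_placement, train)
    s2 <- stage_forward(plan, s1$y, blocks[[b]]$conv2, blocks[[b]]$bn2,
                        state$bn[[b]]$bn2, cfg$bn_placement, train)
    state$bn[[b]]$bn1 <- s1$run
    state$bn[[b]]$bn2 <- s2$run
    f <- s2$y
    bcache[[b]] <- list(s1 = s1$cache, s2 = s2$cache, plan = plan)
    if (cfg$pooling == "graclus") {
      lev <- input$levels[[b + 1L]]
      pm <- pool_max(f, lev$cl, lev$n)
      rec <- pool_record(lev$cl, f, input$levels[[b]]$pos, lev$pos,
                         level = b, check = FALSE)
      records[[b]] <- rec
      pcache[[b]] <- list(argmax = pm$argmax, n_fine = nrow(f),
                          record = rec)
      x <- pm$values
    } else if (cfg$pooling == "topk") {
      g_here <- feature_graph(f, cur_pos,
                              if (b == 1L) cur_graph$edges else
                                pcache[[b - 1L]]$edges,
                              pseudo = if (b == 1L) cur_graph$pseudo else
                                pcache[[b - 1L]]$pseudo,
                              check = FALSE)
      tp <- topk_pool(g_here, model$params$topk[[b]]$projection,
                      cfg$topk_ratio, level = b)
      records[[b]] <- tp$record
      ke <- knn_edges(cur_pos, tp$coarse$pos, cfg$knn_k, cfg$epsilon)
      pcache[[b]] <- list(keep = tp$keep, score = tp$score,
                          graph = g_here, ke = ke,
                          edges = tp$coarse$edges,
                          pseudo = tp$coarse$pseudo,
                          next_plan = plan_for_graph(tp$coarse, cfg))
      cur_pos <- tp$coarse$pos
      x <- tp$coarse$x
    } else {
      pcache[[b]] <- list()
      x <- f
    }
    taps[[b]] <- x
    graphs_n <- c(graphs_n, nrow(x))
  }
  # decoder
  sc <- model$params$scores
  sk <- skip_levels(cfg)
  dcache <- list()
  s <- score_forward(taps[[depth]], sc$top)
  dcache$top_x <- taps[[depth]]
  if (cfg$pooling == "none") {
    for (l in sk) {
      s <- s + score_forward(taps[[l]], sc[[paste0("v", l)]])
      dcache[[paste0("x", l)]] <- taps[[l]]
    }
  } else {
    for (l in depth:1L) {
      s <- unpool_step(s, l, cfg, records, pcache, input)
      if ((l - 1L) %in% sk) {
        s <- s + score_forward(taps[[l - 1L]], sc[[paste0("v", l - 1L)]])
        dcache[[paste0("x", l - 1L)]] <- taps[[l - 1L]]
      }
    }
  }
  prob <- 1 / (1 + exp(-s))
  structure(list(prob = prob, score0 = s, records = records,
                 graphs_n = graphs_n, state = state, input = input,
                 bcache = bcache, pcache = pcache, dcache = dcache,
                 taps_n = vapply(taps, nrow, numeric(1))),
            class = "gfcn_trace")
}

unpool_step <- function(s, l, cfg, records, pcache, input) {
  s <- matrix(s, ncol = 1)
  if (cfg$unpooling == "isotropic") {
    as.numeric(isotropic_unpool(s, records[[l]]))
  } else if (cfg$unpooling == "proportional") {
    as.numeric(proportional_unpool(
      s, records[[l]], unpool_config("proportional",
                                     epsilon = cfg$epsilon)))
  } else {
    as.numeric(rowsum_into(s[pcache[[l]]$ke$coarse, , drop = FALSE] *
                             pcache[[l]]$ke$w,
                           pcache[[l]]$ke$fine, pcache[[l]]$ke$n_fine))
  }
}

unpool_step_backward <- function(ds, l, cfg, records, pcache) {
  ds <- matrix(ds, ncol = 1)
  if (cfg$unpooling == "isotropic") {
    as.numeric(isotropic_unpool_backward(ds, records[[l]]))
  } else if (cfg$unpooling == "proportional") {
    as.numeric(proportional_unpool_backward(ds, records[[l]], 1L,
                                            cfg$epsilon))
  } else {
    as.numeric(knn_unpool_backward(ds, pcache[[l]]$ke))
  }
}

#' Backpropagate through the network
#'
#' Given the gradient of a loss with respect to the pre-sigmoid `V0` score
#' map, returns gradients for every trainable parameter.  The proportional
#' unpooling weights are treated as constants (gradient-stop), matching the
#' forward definition.
#'
#' @param model a `gfcn_model`.
#' @param trace the `gfcn_trace` from a `train = TRUE` forward pass.
#' @param dscore0 numeric vector, d loss / d score0.
#' @return Gradients mirroring `model$params`.
#' @keywords internal
gfcn_backward <- function(model, trace, dscore0) {
  cfg <- model$config
  depth <- cfg$depth
  blocks <- model$params$blocks
  sc <- model$params$scores
  sk <- skip_levels(cfg)
  grads <- list(blocks = vector("list", depth), scores = list())
  dtap <- vector("list", depth)
  zero_tap <- function(l) matrix(0, trace$taps_n[l],
                                 block_widths(cfg)$out[l])
  # decoder reverse
  if (cfg$pooling == "none") {
    ds <- dscore0
    for (l in sk) {
      sb <- score_backward(trace$dcache[[paste0("x", l)]],
                           sc[[paste0("v", l)]], ds)
      grads$scores[[paste0("v", l)]] <- list(w = sb$dw, b = sb$db)
      dtap[[l]] <- sb$dx
    }
    sb <- score_backward(trace$dcache$top_x, sc$top, ds)
    grads$scores$top <- list(w = sb$dw, b = sb$db)
    dtap[[depth]] <- if (depth %in% sk) dtap[[depth]] + sb$dx else sb$dx
  } else {
    ds <- dscore0
    for (l in 1L:depth) {
      if ((l - 1L) >= 1L && (l - 1L) %in% sk) {
        sb <- score_backward(trace$dcache[[paste0("x", l - 1L)]],
                             sc[[paste0("v", l - 1L)]], ds)
        grads$scores[[paste0("v", l - 1L)]] <- list(w = sb$dw, b = sb$db)
        dtap[[l - 1L]] <- sb$dx
      }
      ds <- unpool_step_backward(ds, l, cfg, trace$records, trace$pcache)
    }
    sb <- score_backward(trace$dcache$top_x, sc$top, ds)
    grads$scores$top <- list(w = sb$dw, b = sb$db)
    dtap[[depth]] <- sb$dx
  }
  # encoder reverse
  if (cfg$pooling == "topk")
    grads$topk <- vector("list", depth)
  g <- dtap[[depth]]
  for (b in depth:1L) {
    if (is.null(g)) g <- zero_tap(b)
    pc <- trace$pcache[[b]]
    if (cfg$pooling == "graclus") {
      df <- pool_max_backward(g, pc$argmax, pc$n_fine)
    } else if (cfg$pooling == "topk") {
      tb <- topk_backward(pc$graph, pc$keep, pc$score,
                          model$params$topk[[b]]$projection, g)
      df <- tb$dx
      grads$topk[[b]] <- list(projection = tb$dprojection)
    } else {
      df <- g
    }
    plan <- trace$bcache[[b]]$plan
    s2b <- stage_backward(plan, trace$bcache[[b]]$s2, blocks[[b]]$conv2,
                          blocks[[b]]$bn2, cfg$bn_placement, df)
    s1b <- stage_backward(plan, trace$bcache[[b]]$s1, blocks[[b]]$conv1,
                          blocks[[b]]$bn1, cfg$bn_placement, s2b$dx)
    grads$blocks[[b]] <- list(conv1 = s1b$conv, bn1 = s1b$bn,
                              conv2 = s2b$conv, bn2 = s2b$bn)
    g <- if (b > 1L) {
      gi <- s1b$dx
      if (!is.null(dtap[[b - 1L]])) gi + dtap[[b - 1L]] else gi
    } else NULL
  }
  grads
}

#' Threshold probabilities into a binary node mask
#'
#' @param trace a `gfcn_trace` (or a numeric probability vector).
#' @param threshold decision threshold; a probability equal to the
#'   threshold is labeled 1.
#' @return Integer vector of 0/1 labels, one per `V0` node.
#' @export
predict_mask <- function(trace, threshold = 0.5) {
  p <- if (inherits(trace, "gfcn_trace")) trace$prob else as.numeric(trace)
  as.integer(p >= threshold)
}
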