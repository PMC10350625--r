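# Shared small slice graph for architecture tests.
local({
  spec <- phantom_spec(shape = c(2L, 14L, 14L), n_cases = 1, seed = 21)
  v <- preprocess(make_case(spec, 1))
  assign("arch_graph", slice_to_graph(v, 1, 8L, "brain"),
         envir = topenv())
  assign("arch_volume", v, envir = topenv())
})

test_that("block widths follow the doubling schedule", {
  cfg <- gfcn_config("8s", depth = 4, base_channels = 32)
  bw <- gfcn:::block_widths(cfg)
  expect_equal(bw$out, c(32, 64, 128, 256))
  expect_equal(bw$inp, c(5, 32, 64, 128))
})

test_that("parameter count matches the closed-form schedule", {
  for (depth in c(4L, 5L)) {
    base <- 8L
    cfg <- gfcn_config("32s", depth = depth, base_channels = base,
                       kernel_size = c(5, 5), degree = 1)
    m <- gfcn_init(cfg)
    outs <- base * 2^(seq_len(depth) - 1)
    ins <- c(5, outs[-depth])
    expected <- 0
    for (b in seq_len(depth)) {
      # conv1 + conv2 (25 control points each, root, bias) + two BN layers
      expected <- expected +
        25 * ins[b] * outs[b] + ins[b] * outs[b] + outs[b] +
        25 * outs[b]^2 + outs[b]^2 + outs[b] +
        4 * outs[b]
    }
    expected <- expected + outs[depth] + 1       # top score layer
    expect_equal(n_params(m), expected)
  }
})

test_that("batch-norm placement changes the block output", {
  g <- arch_graph
  outs <- lapply(c("pre", "post"), function(bp) {
    cfg <- gfcn_config("32s", depth = 4, base_channels = 4,
                       bn_placement = bp, seed = 3)
    m <- gfcn_init(cfg)
    gfcn_forward(m, gfcn_prepare(cfg, g), train = TRUE)$prob
  })
  expect_false(isTRUE(all.equal(outs[[1]], outs[[2]])))
})

test_that("output length equals V0 node count for all variant/pooling", {
  g <- arch_graph
  n <- nrow(g$x)
  combos <- list(c("graclus", "isotropic"), c("graclus", "proportional"),
                 c("topk", "knn"), c("none", "none"))
  for (variant in c("32s", "16s", "8s")) for (cb in combos) {
    cfg <- gfcn_config(variant, depth = 4, base_channels = 4,
                       pooling = cb[1],
                       unpooling = if (cb[1] == "none") NULL else cb[2],
                       seed = 5)
    m <- gfcn_init(cfg)
    tr <- gfcn_forward(m, gfcn_prepare(cfg, g), train = FALSE)
    expect_length(tr$prob, n)
    expect_true(all(tr$prob >= 0 & tr$prob <= 1))
    n_rec <- if (cb[1] == "none") 0L else cfg$depth
    expect_length(tr$records, n_rec)
    expect_true(all(diff(tr$graphs_n) <= 0))   # non-increasing levels
  }
})

test_that("pooling none keeps every topology at V0", {
  cfg <- gfcn_config("8s", depth = 4, base_channels = 4,
                     pooling = "none", seed = 2)
  m <- gfcn_init(cfg)
  tr <- gfcn_forward(m, gfcn_prepare(cfg, arch_graph))
  expect_equal(tr$graphs_n, rep(nrow(arch_graph$x), 5))
})

test_that("config invariants reject invalid combinations", {
  expect_error(gfcn_config("8s", depth = 3), "depth >= 4")
  expect_error(gfcn_config("16s", depth = 1), "depth >= 2")
  expect_error(gfcn_config("8s", pooling = "none",
                           unpooling = "isotropic"), "forbids")
  expect_error(gfcn_config("8s", pooling = "topk",
                           unpooling = "isotropic"), "pairs with")
  expect_error(gfcn_config("8s", pooling = "graclus",
                           unpooling = "knn"), "pairs with")
})

test_that("evaluation-mode forward passes are bitwise deterministic", {
  cfg <- gfcn_config("8s", depth = 4, base_channels = 4, seed = 9)
  m <- gfcn_init(cfg)
  inp <- gfcn_prepare(cfg, arch_graph)
  p1 <- gfcn_forward(m, inp, train = FALSE)$prob
  p2 <- gfcn_forward(m, inp, train = FALSE)$prob
  expect_identical(p1, p2)
})

test_that("zeroing the skip score layers reduces 8s and 16s to 32s", {
  g <- arch_graph
  for (unp in c("isotropic", "proportional")) {
    cfg8 <- gfcn_config("8s", depth = 4, base_channels = 4,
                        unpooling = unp, seed = 11)
    m8 <- gfcn_init(cfg8)
    for (nm in c("v3", "v2")) {
      m8$params$scores[[nm]]$w[] <- 0
      m8$params$scores[[nm]]$b <- 0
    }
    m32 <- m8
    m32$config$variant <- "32s"
    inp <- gfcn_prepare(cfg8, g)
    p8 <- gfcn_forward(m8, inp)$prob
    p32 <- gfcn_forward(m32, inp)$prob
    expect_equal(p8, p32, tolerance = 1e-12)

    m16 <- m8
    m16$config$variant <- "16s"
    m16$params$scores$v2 <- list(w = m8$params$scores$v2$w * 0, b = 0)
    p16 <- gfcn_forward(m16, inp)$prob
    expect_equal(p16, p32, tolerance = 1e-12)
  }
})

test_that("the whole network is permutation equivariant in eval mode", {
  g <- arch_graph
  n <- nrow(g$x)
  set.seed(23)
  q <- sample(n)
  gp <- permute_graph(g, q)
  combos <- list(c("graclus", "isotropic"), c("graclus", "proportional"),
                 c("topk", "knn"), c("none", "none"))
  for (cb in combos) {
    cfg <- gfcn_config("8s", depth = 4, base_channels = 4,
                       pooling = cb[1],
                       unpooling = if (cb[1] == "none") NULL else cb[2],
                       seed = 13)
    m <- gfcn_init(cfg)
    p <- gfcn_forward(m, gfcn_prepare(cfg, g))$prob
    pp <- gfcn_forward(m, gfcn_prepare(cfg, gp))$prob
    expect_equal(pp[q], p, tolerance = 1e-5,
                 label = paste("pooling", cb[1]))
  }
})

test_that("predict_mask uses the >= threshold convention", {
  expect_equal(predict_mask(c(0.49, 0.5, 0.51)), c(0L, 1L, 1L))
  expect_equal(predict_mask(rep(0, 4)), rep(0L, 4))
  expect_equal(predict_mask(c(0.2, 0.8), threshold = 0.2), c(1L, 1L))
})

test_that("thresholded node labels map back to a binary slice mask", {
  cfg <- gfcn_config("8s", depth = 4, base_channels = 4, seed = 15)
  m <- gfcn_init(cfg)
  tr <- gfcn_forward(m, gfcn_prepare(cfg, arch_graph))
  lab <- predict_mask(tr)
  sl <- graph_to_slice(arch_graph, lab)
  expect_true(all(sl %in% c(0, 1)))
  expect_equal(sum(sl), sum(lab))
})

test_that("batched forward equals per-slice forward in eval mode", {
  spec <- phantom_spec(shape = c(2L, 12L, 12L), n_cases = 1, seed = 31)
  v <- preprocess(make_case(spec, 1))
  cfg <- gfcn_config("8s", depth = 4, base_channels = 4, seed = 17)
  m <- gfcn_init(cfg)
  inps <- lapply(1:2, function(s)
    gfcn_prepare(cfg, slice_to_graph(v, s, 8L, "brain")))
  bat <- gfcn_batch(inps)
  pb <- gfcn_forward(m, bat)$prob
  p1 <- gfcn_forward(m, inps[[1]])$prob
  p2 <- gfcn_forward(m, inps[[2]])$prob
  expect_equal(pb, c(p1, p2), tolerance = 1e-10)
})
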