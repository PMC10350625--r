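test_that("basis hits single control points at domain corners", {
  cfg <- spline_kernel_config(1, 1, kernel_size = c(2, 2), degree = 1)
  sb <- spline_basis(matrix(c(0, 0), 1, 2), cfg)
  expect_equal(as.numeric(sb$values), c(1, 0, 0, 0))
  expect_equal(sb$index[1, 1], 1L)         # control point (0,0)
  sb11 <- spline_basis(matrix(c(1, 1), 1, 2), cfg)
  nz <- which(sb11$values[1, ] > 0)
  expect_equal(sb11$index[1, nz], 4L)      # control point (1,1)
  expect_equal(sum(sb11$values), 1)
})

test_that("bilinear midpoint spreads weight 0.25 over four points", {
  cfg <- spline_kernel_config(1, 1, kernel_size = c(2, 2), degree = 1)
  sb <- spline_basis(matrix(c(0.5, 0.5), 1, 2), cfg)
  expect_equal(as.numeric(sb$values), rep(0.25, 4))
  expect_setequal(as.integer(sb$index), 1:4)
})

test_that("product basis is a nonnegative partition of unity", {
  set.seed(1)
  for (degree in 1:3) for (k in list(c(degree + 1, degree + 1),
                                     c(5, 5), c(4, 7))) {
    cfg <- spline_kernel_config(1, 1, kernel_size = k, degree = degree)
    u <- matrix(runif(400), 200, 2)
    u[1, ] <- c(0, 0); u[2, ] <- c(1, 1)   # include the corners
    sb <- spline_basis(u, cfg)
    expect_true(all(sb$values >= 0))
    expect_equal(rowSums(sb$values), rep(1, 200), tolerance = 1e-6)
    expect_true(all(sb$index >= 1 & sb$index <= prod(k)))
  }
})

test_that("out-of-range pseudo-coordinates clamp with warning or error", {
  cfg <- spline_kernel_config(1, 1, kernel_size = c(3, 3), degree = 1)
  expect_warning(sb <- spline_basis(matrix(c(-0.01, 1.01), 1, 2), cfg),
                 "clamp")
  expect_equal(sum(sb$values), 1)
  expect_error(spline_basis(matrix(c(-0.01, 0.5), 1, 2), cfg,
                            clamp = "error"), "outside")
})

test_that("forward matches the brute-force per-edge oracle", {
  g <- random_graph(12, p = 0.5, n_features = 3, seed = 7)
  # normalize pseudo into [0,1] is already guaranteed by construction
  for (degree in 1:2) {
    cfg <- spline_kernel_config(3, 4, kernel_size = c(4, 4),
                                degree = degree)
    set.seed(degree)
    params <- spline_conv_params(cfg)
    expect_equal(spline_conv_forward(g, params, cfg),
                 brute_spline_conv(g, params, cfg), tolerance = 1e-10)
  }
})

test_that("a constant kernel collapses to the neighbor mean", {
  g <- grid_graph(5, 5, 8L, seed = 3)
  cfg <- spline_kernel_config(3, 2, kernel_size = c(5, 5), degree = 1,
                              root_weight = FALSE, bias = FALSE)
  wbar <- matrix(rnorm(6), 3, 2)
  params <- list(weight = array(rep(wbar, each = 25), c(25, 3, 2)),
                 root = NULL, bias = NULL)
  out <- spline_conv_forward(g, params, cfg)
  nbr_mean <- t(vapply(seq_len(25), function(i) {
    js <- g$edges[g$edges[, 2] == i, 1]
    colMeans(g$x[js, , drop = FALSE])
  }, numeric(3)))
  expect_equal(out, nbr_mean %*% wbar, tolerance = 1e-6)
})

test_that("zero kernel with identity root is the identity layer", {
  g <- grid_graph(4, 4, 4L, seed = 2)
  cfg <- spline_kernel_config(3, 3, kernel_size = c(5, 5), degree = 1)
  params <- list(weight = array(0, c(25, 3, 3)), root = diag(3),
                 bias = NULL)
  expect_equal(spline_conv_forward(g, params, cfg), g$x)
})

test_that("isolated nodes receive only root and bias", {
  x <- matrix(rnorm(3), 1, 3)
  g <- feature_graph(x, matrix(0, 1, 2), matrix(integer(0), 0, 2))
  cfg <- spline_kernel_config(3, 3, kernel_size = c(3, 3), degree = 1)
  params <- list(weight = array(rnorm(27), c(9, 3, 3)), root = diag(3),
                 bias = c(1, 2, 3))
  expect_equal(as.numeric(spline_conv_forward(g, params, cfg)),
               as.numeric(x) + c(1, 2, 3))
})

test_that("convolution is permutation equivariant and linear", {
  g <- random_graph(10, p = 0.5, n_features = 3, seed = 4)
  cfg <- spline_kernel_config(3, 2, kernel_size = c(5, 5), degree = 1)
  set.seed(5)
  params <- spline_conv_params(cfg)
  out <- spline_conv_forward(g, params, cfg)
  q <- sample(10)
  gp <- permute_graph(g, q)
  outp <- spline_conv_forward(gp, params, cfg)
  expect_equal(outp[q, ], out, tolerance = 1e-6)
  # linearity in the node features
  g2 <- g; g2$x <- matrix(rnorm(30), 10, 3)
  ga <- g; ga$x <- 2 * g$x + 3 * g2$x
  expect_equal(spline_conv_forward(ga, params, cfg),
               2 * out + 3 * spline_conv_forward(g2, params, cfg),
               tolerance = 1e-8)
})

test_that("analytic gradients match central finite differences", {
  g <- random_graph(8, p = 0.6, n_features = 2, seed = 6)
  cfg <- spline_kernel_config(2, 3, kernel_size = c(3, 3), degree = 1)
  set.seed(8)
  params <- spline_conv_params(cfg)
  plan <- gfcn:::make_conv_plan(g$edges, g$pseudo, 8, cfg)
  set.seed(9)
  gout <- matrix(rnorm(24), 8, 3)      # upstream gradient
  loss <- function(pa, x) sum(gout * gfcn:::conv_forward_plan(plan, x, pa))
  grads <- gfcn:::conv_backward_plan(plan, g$x, params, gout)
  eps <- 1e-6
  check <- function(value, get, set) {
    for (i in seq_along(value)) {
      p2 <- set(value, i, eps); p3 <- set(value, i, -eps)
      fd <- (loss(p2$params, p2$x) - loss(p3$params, p3$x)) / (2 * eps)
      expect_equal(get(i), fd, tolerance = 1e-4)
    }
  }
  # weights
  check(params$weight,
        function(i) grads$dweight[i],
        function(v, i, e) { p <- params; p$weight[i] <- p$weight[i] + e
          list(params = p, x = g$x) })
  # root
  check(params$root,
        function(i) grads$droot[i],
        function(v, i, e) { p <- params; p$root[i] <- p$root[i] + e
          list(params = p, x = g$x) })
  # bias
  check(params$bias,
        function(i) grads$dbias[i],
        function(v, i, e) { p <- params; p$bias[i] <- p$bias[i] + e
          list(params = p, x = g$x) })
  # input features
  check(g$x,
        function(i) grads$dx[i],
        function(v, i, e) { x <- g$x; x[i] <- x[i] + e
          list(params = params, x = x) })
})
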