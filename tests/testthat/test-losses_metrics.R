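test_that("soft Dice loss handles perfect, empty and uniform cases", {
  g <- c(1, 0, 1, 1, 0)
  expect_equal(soft_dice_loss(g, g), 0)
  expect_equal(soft_dice_loss(rep(0, 4), rep(0, 4)), 0)
  # p = 0.5 uniform, m positives of N, smooth 0: 1 - m/(0.25N + m)
  n <- 40; m <- 12
  y <- c(rep(1, m), rep(0, n - m))
  expect_equal(soft_dice_loss(rep(0.5, n), y, smooth = 0),
               1 - m / (0.25 * n + m))
  expect_error(soft_dice_loss(c(0.5, 0.5), c(1)), "length")
})

test_that("soft Dice gradient matches finite differences", {
  set.seed(13)
  p <- runif(15); y <- rbinom(15, 1, 0.4)
  gr <- gfcn:::soft_dice_grad(p, y)
  eps <- 1e-6
  for (i in c(1, 7, 15)) {
    p2 <- p; p2[i] <- p2[i] + eps
    p3 <- p; p3[i] <- p3[i] - eps
    fd <- (soft_dice_loss(p2, y) - soft_dice_loss(p3, y)) / (2 * eps)
    expect_equal(gr[i], fd, tolerance = 1e-5)
  }
})

test_that("binary soft Dice at smooth 0 equals 1 - standard DCS", {
  set.seed(14)
  for (r in 1:10) {
    p <- rbinom(30, 1, 0.5); y <- rbinom(30, 1, 0.4)
    if (sum(p) + sum(y) == 0) next
    cts <- confusion_counts(p, y)
    expect_equal(soft_dice_loss(p, y, smooth = 0), 1 - dcs(cts))
  }
})

test_that("confusion counts match a brute-force voxel tally", {
  set.seed(15)
  a <- array(rbinom(60, 1, 0.5), c(3, 4, 5))
  b <- array(rbinom(60, 1, 0.3), c(3, 4, 5))
  cts <- confusion_counts(a, b)
  tally <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (i in seq_along(a)) {
    k <- if (a[i] == 1 && b[i] == 1) "TP" else if (a[i] == 0 && b[i] == 0)
      "TN" else if (a[i] == 1) "FP" else "FN"
    tally[k] <- tally[k] + 1
  }
  expect_equal(cts, tally)
  expect_equal(sum(cts), 60)
  # identical masks; complementary masks
  expect_equal(unname(confusion_counts(b, b)[c("FP", "FN")]), c(0, 0))
  expect_equal(unname(confusion_counts(1 - b, b)[c("TP", "TN")]),
               c(0, 0))
  expect_error(confusion_counts(c(0, 2), c(0, 1)), "binary")
})

test_that("dcs implements both printed and standard formulas", {
  expect_equal(dcs(c(TP = 5, TN = 90, FP = 0, FN = 0)), 1)
  expect_equal(dcs(c(TP = 0, TN = 90, FP = 5, FN = 5)), 0)
  expect_equal(dcs(c(TP = 3, TN = 0, FP = 1, FN = 2)), 6 / 9)
  expect_equal(dcs(c(TP = 3, TN = 4, FP = 1, FN = 2),
                   formula = "as_printed"), 6 / (6 + 4 + 2))
  expect_equal(dcs(c(TP = 0, TN = 10, FP = 0, FN = 0)), 1)  # empty vs empty
})

test_that("precision/recall/accuracy follow the empty-set conventions", {
  expect_equal(unname(precision_recall_accuracy(
    c(TP = 4, TN = 6, FP = 0, FN = 0))), c(1, 1, 1))
  pra <- precision_recall_accuracy(c(TP = 0, TN = 5, FP = 0, FN = 5))
  expect_equal(pra[["recall"]], 0)
  expect_equal(pra[["precision"]], 1)     # nothing predicted
  pra2 <- precision_recall_accuracy(c(TP = 3, TN = 4, FP = 1, FN = 2))
  expect_equal(unname(pra2), c(0.75, 0.6, 0.7))
})

test_that("DCS equals the precision/recall harmonic mean when defined", {
  set.seed(16)
  for (r in 1:10) {
    cts <- c(TP = sample(1:20, 1), TN = sample(0:20, 1),
             FP = sample(1:10, 1), FN = sample(1:10, 1))
    pra <- precision_recall_accuracy(cts)
    pr <- pra[["precision"]]; rc <- pra[["recall"]]
    expect_equal(dcs(cts), 2 * pr * rc / (pr + rc))
  }
})

test_that("hausdorff matches the double-loop oracle", {
  a <- array(0, c(8, 8)); a[1, 1] <- 1
  b <- array(0, c(8, 8)); b[4, 5] <- 1
  expect_equal(hausdorff(a, b), 5)        # 3-4-5 single-voxel case
  expect_equal(hausdorff(a, a), 0)
  set.seed(17)
  for (r in 1:50) {
    a <- array(rbinom(64, 1, 0.2), c(8, 8))
    b <- array(rbinom(64, 1, 0.2), c(8, 8))
    expect_equal(hausdorff(a, b), brute_hausdorff(a, b))
    expect_equal(hausdorff(a, b), hausdorff(b, a))   # symmetry
  }
  # anisotropic spacing and 3-D masks
  a3 <- array(rbinom(60, 1, 0.3), c(3, 4, 5))
  b3 <- array(rbinom(60, 1, 0.3), c(3, 4, 5))
  sp <- c(5, 1, 2)
  expect_equal(hausdorff(a3, b3, sp), brute_hausdorff(a3, b3, sp))
  # empty conventions
  z <- array(0, c(8, 8))
  expect_equal(hausdorff(z, z), 0)
  expect_equal(hausdorff(z, b), sqrt(2) * 8)   # image diagonal
})

test_that("hausdorff never increases when the far mask point is absorbed", {
  a <- array(0, c(10, 10)); a[2, 2] <- 1
  b <- array(0, c(10, 10)); b[2, 2] <- 1; b[9, 9] <- 1
  h1 <- hausdorff(a, b)
  a2 <- a; a2[8, 8] <- 1      # dilate prediction toward the far point
  expect_lte(hausdorff(a2, b), h1)
})

test_that("cod implements the printed formula and sentinels", {
  set.seed(18)
  y <- rbinom(25, 1, 0.4); p <- runif(25)
  direct <- 1 - sum((p - y)^2) / sum((p - mean(y))^2)
  expect_equal(cod(p, y), direct)
  r2 <- 1 - sum((p - y)^2) / sum((y - mean(y))^2)
  expect_equal(cod(p, y, formula = "standard_r2"), r2)
  expect_equal(cod(y, y), 1)
  # constant prediction at E[y] with non-constant truth: sentinel
  expect_equal(cod(rep(mean(y), 25), y), -Inf)
})

test_that("metrics are invariant to simultaneous spatial permutation", {
  set.seed(19)
  a <- array(rbinom(36, 1, 0.4), c(6, 6))
  b <- array(rbinom(36, 1, 0.4), c(6, 6))
  q <- sample(36)
  ap <- array(a[q], c(6, 6)); bp <- array(b[q], c(6, 6))
  expect_equal(dcs(confusion_counts(ap, bp)), dcs(confusion_counts(a, b)))
  expect_equal(precision_recall_accuracy(confusion_counts(ap, bp)),
               precision_recall_accuracy(confusion_counts(a, b)))
  expect_equal(cod(as.numeric(ap), bp), cod(as.numeric(a), b))
})

test_that("aggregation averages slices then cases, and stratifies", {
  rows1 <- data.frame(dcs = 0.5, accuracy = 0.9, precision = 0.5,
                      recall = 0.5, hd = 2, cod = 0.1,
                      lesion_voxels = 10, case = "a", slice = 1)
  r_s <- aggregate_metrics(rows1, "sample_wise")
  r_v <- aggregate_metrics(transform(rows1, slice = NULL),
                           "volume_wise")
  expect_equal(r_s$summary, r_v$summary)  # one case, one slice: agree
  # tercile strata: 3 cases with counts 10/100/1000, one per stratum
  rows3 <- data.frame(dcs = c(0.2, 0.5, 0.8), accuracy = 0.9,
                      precision = 0.5, recall = 0.5, hd = 1,
                      cod = c(0.1, -Inf, 0.3),
                      lesion_voxels = c(10, 100, 1000),
                      case = c("a", "b", "c"))
  rv <- aggregate_metrics(rows3, "volume_wise")
  expect_equal(as.character(rv$strata$stratum),
               c("small", "medium", "large"))
  expect_equal(rv$strata$n, c(1, 1, 1))
  expect_equal(rv$cod_excluded, 1)
  expect_equal(rv$summary[["cod"]], mean(c(0.1, 0.3)))  # sentinel dropped
  # sample-wise: slices averaged within case before cases are averaged
  rows4 <- data.frame(dcs = c(0.2, 0.4, 0.9), accuracy = 1,
                      precision = 1, recall = 1, hd = 0, cod = 1,
                      lesion_voxels = 5,
                      case = c("a", "a", "b"), slice = c(1, 2, 1))
  r4 <- aggregate_metrics(rows4, "sample_wise")
  expect_equal(r4$summary[["dcs"]], mean(c(mean(c(0.2, 0.4)), 0.9)))
})

test_that("volume-wise DCS equals DCS of the concatenated case voxels", {
  set.seed(20)
  cases <- lapply(1:3, function(i) {
    list(pred = array(rbinom(48, 1, 0.4), c(3, 4, 4)),
         truth = array(rbinom(48, 1, 0.4), c(3, 4, 4)))
  })
  rows <- do.call(rbind, lapply(seq_along(cases), function(i) {
    r <- gfcn:::metrics_row(cases[[i]]$pred, cases[[i]]$truth)
    r$case <- as.character(i)
    r
  }))
  rv <- aggregate_metrics(rows, "volume_wise")
  oracle <- mean(vapply(cases, function(cs)
    dcs(confusion_counts(as.numeric(cs$pred), as.numeric(cs$truth))),
    numeric(1)))
  expect_equal(rv$summary[["dcs"]], oracle)
})
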