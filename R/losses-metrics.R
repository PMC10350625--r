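#' Soft Dice loss
#'
#' `1 - (2 * sum(p*g) + smooth) / (sum(p^2) + sum(g^2) + smooth)`,
#' differentiable in the probabilities.  With binary predictions and
#' `smooth = 0` this equals one minus the standard Dice coefficient; the
#' default `smooth = 1` rescues slices with empty masks (loss 0 when both
#' prediction and target are all zero).
#'
#' @param probabilities numeric vector in `[0,1]`.
#' @param target binary vector of the same length.
#' @param smooth nonnegative smoothing constant (default 1).
#' @return Scalar loss.
#' @export
soft_dice_loss <- function(probabilities, target, smooth = 1) {
  if (length(probabilities) != length(target))
    stop("length mismatch between probabilities and target")
  num <- 2 * sum(probabilities * target) + smooth
  den <- sum(probabilities^2) + sum(target^2) + smooth
  1 - num / den
}

# d loss / d probabilities
soft_dice_grad <- function(probabilities, target, smooth = 1) {
  num <- 2 * sum(probabilities * target) + smooth
  den <- sum(probabilities^2) + sum(target^2) + smooth
  -(2 * target * den - num * 2 * probabilities) / den^2
}

#' Voxelwise confusion counts
#'
#' @param pred_mask,true_mask binary arrays of identical shape.
#' @return Named numeric vector `(TP, TN, FP, FN)` summing to the voxel
#'   count.
#' @export
confusion_counts <- function(pred_mask, true_mask) {
  if (!identical(dim(as.array(pred_mask)), dim(as.array(true_mask))) &&
      length(pred_mask) != length(true_mask))
    stop("shape mismatch")
  check_binary(pred_mask, "pred_mask")
  check_binary(true_mask, "true_mask")
  p <- round(as.numeric(pred_mask)); g <- round(as.numeric(true_mask))
  c(TP = sum(p == 1 & g == 1), TN = sum(p == 0 & g == 0),
    FP = sum(p == 1 & g == 0), FN = sum(p == 0 & g == 1))
}

#' Dice coefficient score from confusion counts
#'
#' The standard Dice coefficient is `2TP / (2TP + FP + FN)` (default).  The
#' `"as_printed"` variant `2TP / (2TP + TN + FN)` substitutes TN for FP and
#' is retained for fidelity to one published formulation; its magnitudes
#' are inconsistent with reported accuracy on large images, so it is not
#' the default.  Empty-versus-empty (all counts of the union zero) is
#' defined as 1.
#'
#' @param counts named vector from [confusion_counts()].
#' @param formula `"standard"` or `"as_printed"`.
#' @return Scalar in `[0,1]`.
#' @export
dcs <- function(counts, formula = c("standard", "as_printed")) {
  formula <- match.arg(formula)
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  tn <- counts[["TN"]]
  den <- if (formula == "standard") 2 * tp + fp + fn else 2 * tp + tn + fn
  if (formula == "standard" && tp + fp + fn == 0) return(1)
  if (den == 0) return(if (tp == 0) 1 else 0)
  2 * tp / den
}

#' Precision, recall and accuracy from confusion counts
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`,
#' `accuracy = (TP + TN) / total`.  A 0/0 ratio is defined as 1 when the
#' corresponding reference set is empty (nothing to find or nothing
#' predicted).
#'
#' @param counts named vector from [confusion_counts()].
#' @return Named vector `(precision, recall, accuracy)`.
#' @export
precision_recall_accuracy <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  total <- tp + tn + fp + fn
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  accuracy <- if (total == 0) 1 else (tp + tn) / total
  c(precision = precision, recall = recall, accuracy = accuracy)
}

mask_coords <- function(mask, spacing) {
  mask <- as.array(mask)
  nd <- length(dim(mask))
  if (is.null(dim(mask))) { mask <- array(mask); nd <- 1L }
  wh <- which(mask == 1, arr.ind = TRUE)
  if (is.vector(wh)) wh <- matrix(wh, ncol = 1)
  sweep(matrix(as.numeric(wh), ncol = nd), 2,
        as.numeric(spacing[seq_len(nd)]), "*")
}

directed_hausdorff <- function(a, b) {
  # max over rows of a of the min distance to b
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(max(pmax(apply(d2, 1, min), 0)))
}

#' Hausdorff distance between binary masks
#'
#' Symmetric Hausdorff distance between the foreground voxel coordinate
#' sets, scaled by the voxel spacing.  By convention: 0 when both masks are
#' empty; the image diagonal length (a large miss penalty) when exactly one
#' is empty.  Computed over all foreground voxels by default;
#' `boundary_only = TRUE` first strips interior voxels (those whose full
#' orthogonal neighborhood is foreground).
#'
#' @param pred_mask,true_mask binary arrays of identical shape.
#' @param spacing voxel size per axis (recycled to the mask dimensionality).
#' @param boundary_only use only boundary voxels.
#' @return Nonnegative scalar distance.
#' @export
hausdorff <- function(pred_mask, true_mask, spacing = 1,
                      boundary_only = FALSE) {
  pred_mask <- as.array(pred_mask); true_mask <- as.array(true_mask)
  if (!identical(dim(pred_mask), dim(true_mask)))
    stop("shape mismatch")
  dims <- dim(pred_mask)
  spacing <- rep(spacing, length.out = length(dims))
  if (boundary_only) {
    pred_mask <- boundary_mask(pred_mask)
    true_mask <- boundary_mask(true_mask)
  }
  a <- mask_coords(pred_mask, spacing)
  b <- mask_coords(true_mask, spacing)
  if (nrow(a) == 0 && nrow(b) == 0) return(0)
  if (nrow(a) == 0 || nrow(b) == 0)
    return(sqrt(sum((dims * spacing)^2)))
  max(directed_hausdorff(a, b), directed_hausdorff(b, a))
}

boundary_mask <- function(mask) {
  dims <- dim(mask)
  interior <- array(TRUE, dims)
  nd <- length(dims)
  idx <- lapply(dims, seq_len)
  for (ax in seq_len(nd)) {
    for (shift in c(-1L, 1L)) {
      shifted <- array(0, dims)
      src <- idx; dst <- idx
      if (shift == 1L) {
        src[[ax]] <- 1:(dims[ax] - 1); dst[[ax]] <- 2:dims[ax]
      } else {
        src[[ax]] <- 2:dims[ax]; dst[[ax]] <- 1:(dims[ax] - 1)
      }
      shifted <- do.call(`[<-`, c(list(shifted), dst,
                                  list(do.call(`[`, c(list(mask), src)))))
      interior <- interior & shifted == 1
    }
  }
  out <- mask
  out[interior] <- 0
  out
}

#' Coefficient of determination
#'
#' The printed variant (default) normalizes the residual sum of squares by
#' the deviations of the *prediction* from the truth's mean:
#' `1 - sum((yhat - y)^2) / sum((yhat - mean(y))^2)`.  The conventional R
#' squared (`"standard_r2"`) normalizes by `sum((y - mean(y))^2)`.  A zero
#' denominator returns `-Inf` as a sentinel; aggregation excludes such
#' values and counts them.
#'
#' @param pred_prob numeric predictions.
#' @param true_mask numeric/binary reference of the same length.
#' @param formula `"as_printed"` or `"standard_r2"`.
#' @return Scalar `<= 1`, possibly `-Inf`.
#' @export
cod <- function(pred_prob, true_mask,
                formula = c("as_printed", "standard_r2")) {
  formula <- match.arg(formula)
  y <- as.numeric(true_mask); yhat <- as.numeric(pred_prob)
  if (length(y) != length(yhat)) stop("length mismatch")
  ey <- mean(y)
  den <- if (formula == "as_printed") sum((yhat - ey)^2)
         else sum((y - ey)^2)
  num <- sum((yhat - y)^2)
  if (den == 0) return(if (num == 0) 1 else -Inf)
  1 - num / den
}

METRIC_COLS <- c("dcs", "accuracy", "precision", "recall", "hd", "cod")

# One row of metrics for a mask pair (+ optional probabilities for COD).
metrics_row <- function(pred_mask, true_mask, spacing = 1,
                        pred_prob = NULL) {
  cts <- confusion_counts(pred_mask, true_mask)
  pra <- precision_recall_accuracy(cts)
  yhat <- if (is.null(pred_prob)) as.numeric(pred_mask)
          else as.numeric(pred_prob)
  data.frame(dcs = dcs(cts), accuracy = pra[["accuracy"]],
             precision = pra[["precision"]], recall = pra[["recall"]],
             hd = hausdorff(pred_mask, true_mask, spacing),
             cod = cod(yhat, true_mask),
             lesion_voxels = sum(round(as.numeric(true_mask))))
}

#' Lesion-size strata from per-case lesion voxel counts
#'
#' Tercile cut (small/medium/large) of the per-case lesion voxel counts.
#'
#' @param lesion_voxels numeric vector of per-case counts.
#' @return Factor with levels `small`, `medium`, `large`.
#' @export
size_strata <- function(lesion_voxels) {
  qs <- stats::quantile(lesion_voxels, c(1, 2) / 3, names = FALSE)
  cut(lesion_voxels, breaks = c(-Inf, qs, Inf),
      labels = c("small", "medium", "large"))
}

#' Aggregate per-unit metric rows
#'
#' `sample_wise`: rows are per-slice; metrics are averaged over the slices
#' of each group (a batch or case) and then over groups.  `volume_wise`:
#' rows are per-case (computed on the stacked case volume) and averaged
#' over cases.  Rows with `-Inf` COD sentinels are excluded from the COD
#' average and counted.  When per-case lesion voxel counts are available,
#' per-stratum averages (tercile cut: small/medium/large) are appended.
#'
#' @param rows data frame with metric columns, a `case` column, and
#'   `lesion_voxels`; sample-wise rows also carry `slice`.
#' @param mode `"sample_wise"` or `"volume_wise"`.
#' @return An object of class `metrics_report`: list with `summary` (overall
#'   means), `strata` (per-stratum means or `NULL`), `rows`, `mode`, and
#'   `cod_excluded` (sentinel count).
#' @export
aggregate_metrics <- function(rows, mode = c("sample_wise",
                                             "volume_wise")) {
  mode <- match.arg(mode)
  if (!nrow(rows)) stop("no metric rows to aggregate")
  mean_metrics <- function(d) {
    out <- vapply(METRIC_COLS, function(cn) {
      v <- d[[cn]]
      if (cn == "cod") v <- v[is.finite(v)]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    out
  }
  if (mode == "sample_wise") {
    groups <- split(rows, rows$case)
    per_group <- t(vapply(groups, mean_metrics,
                          numeric(length(METRIC_COLS))))
    summary <- colMeans(per_group, na.rm = TRUE)
  } else {
    summary <- mean_metrics(rows)
  }
  strata <- NULL
  if (mode == "volume_wise" && nrow(rows) >= 3) {
    st <- size_strata(rows$lesion_voxels)
    strata <- do.call(rbind, lapply(levels(st), function(lv) {
      d <- rows[st == lv, , drop = FALSE]
      if (!nrow(d)) return(NULL)
      cbind(data.frame(stratum = lv, n = nrow(d)),
            as.data.frame(t(mean_metrics(d))))
    }))
  }
  structure(list(summary = summary, strata = strata, rows = rows,
                 mode = mode,
                 cod_excluded = sum(!is.finite(rows$cod))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report (", x$mode, ", ", nrow(x$rows), " units",
      if (x$cod_excluded) paste0(", ", x$cod_excluded,
                                 " COD sentinels excluded"),
      ")\n", sep = "")
  print(round(x$summary, 4))
  if (!is.null(x$strata)) {
    cat("by lesion size stratum:\n")
    print(x$strata, row.names = FALSE)
  }
  invisible(x)
}
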