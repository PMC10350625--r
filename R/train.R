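#' Training configuration
#'
#' Two protocols are provided.  `"ablation"` mirrors the fixed-rate regime
#' used for architecture comparisons: a constant learning rate (default
#' 1e-6) and 100 epochs.  `"comparison"` is the full protocol: Adam with
#' the learning rate divided by 10 after `lr_decay_epoch` epochs, early
#' stopping on the validation Dice score, and a maximum of 300 epochs.
#' Batches hold 4 slices; `steps_per_epoch` optionally caps the number of
#' optimization steps per epoch (45 reproduces the 100-epochs-=-4500-steps
#' accounting at batch 4).
#'
#' @param mode `"comparison"` (default) or `"ablation"`.
#' @param epochs maximum epochs; defaults 300 (comparison) / 100
#'   (ablation).
#' @param batch_size slices per optimization step (default 4).
#' @param lr learning rate; defaults 1e-3 (comparison) / 1e-6 (ablation,
#'   constant).
#' @param lr_decay_epoch,lr_decay_factor comparison-mode decay (after
#'   epoch 100, factor 0.1); ignored in ablation mode.
#' @param patience early-stopping patience in epochs on the validation
#'   volume-wise Dice score (default 25); `Inf` disables early stopping.
#' @param threshold probability threshold for predicted masks.
#' @param folds folds for [gfcn_crossvalidate()].
#' @param steps_per_epoch optional cap on steps per epoch.
#' @param smooth soft Dice smoothing constant.
#' @param seed seed controlling data order (model initialization is seeded
#'   by the model config).
#' @param verbose print one line per epoch.
#' @return An object of class `train_config`.
#' @export
train_config <- function(mode = c("comparison", "ablation"),
                         epochs = NULL, batch_size = 4L, lr = NULL,
                         lr_decay_epoch = 100L, lr_decay_factor = 0.1,
                         patience = 25L, threshold = 0.5, folds = 4L,
                         steps_per_epoch = NULL, smooth = 1,
                         seed = 1L, verbose = FALSE) {
  mode <- match.arg(mode)
  if (is.null(epochs)) epochs <- if (mode == "ablation") 100L else 300L
  if (is.null(lr)) lr <- if (mode == "ablation") 1e-6 else 1e-3
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (lr <= 0) stop("lr must be positive")
  if (folds < 2L) stop("folds must be >= 2 for cross-validation")
  structure(list(mode = mode, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_decay_epoch = as.integer(lr_decay_epoch),
                 lr_decay_factor = lr_decay_factor, patience = patience,
                 threshold = threshold, folds = as.integer(folds),
                 steps_per_epoch = steps_per_epoch, smooth = smooth,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

# ---- Adam over nested parameter lists -------------------------------------

nested_zero <- function(x) {
  if (is.list(x)) lapply(x, nested_zero)
  else if (is.numeric(x)) x * 0
  else x
}

adam_init <- function(params) {
  list(m = nested_zero(params), v = nested_zero(params), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    if (is.null(p) || !is.numeric(p)) return(list(p = p, m = m, v = v))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  r <- upd(params, grads, opt$m, opt$v)
  list(params = r$p, opt = list(m = r$m, v = r$v, t = opt$t))
}

# ---- slice preparation ----------------------------------------------------

# Preprocess a case and prepare every slice with brain support.
prepare_case_slices <- function(config, volume) {
  vol <- if (isTRUE(attr(volume, "preprocessed"))) volume
         else preprocess(volume)
  d <- dim(vol$channels)
  out <- list()
  for (s in seq_len(d[2])) {
    g <- tryCatch(slice_to_graph(vol, s, config$connectivity,
                                 config$support),
                  gfcn_empty_graph = function(e) NULL)
    if (is.null(g)) next
    target <- vol$mask[s, , ][g$pixel_index]
    out[[length(out) + 1L]] <- gfcn_prepare(config, g, target = target)
  }
  out
}

# ---- training -------------------------------------------------------------

#' Train a graph FCN on a set of cases
#'
#' Slice-wise training with the soft Dice loss and Adam.  Each epoch
#' shuffles the training slices (seeded), batches them as disjoint graph
#' unions, and logs validation metrics in both aggregation schemes.  The
#' returned model is the checkpoint with the highest validation
#' volume-wise Dice score, never simply the last epoch.
#'
#' @param model_config a [gfcn_config()].
#' @param tc a [train_config()].
#' @param cases named list of [case_volume()] objects.
#' @param splits list with character vectors `train` and `val` of case
#'   ids.
#' @return An object of class `gfcn_fit`: list with `model` (best
#'   checkpoint), `last_model`, `history` (one row per epoch: mean training
#'   loss, sample-wise and volume-wise validation metrics), `best_epoch`,
#'   `model_config`, `train_config`.
#' @export
gfcn_train <- function(model_config, tc, cases, splits) {
  stopifnot(inherits(model_config, "gfcn_config"),
            inherits(tc, "train_config"))
  if (!length(splits$train)) stop("empty training split")
  if (length(intersect(splits$train, splits$val)))
    stop("training and validation splits overlap")
  train_slices <- list()
  for (id in splits$train)
    train_slices <- c(train_slices,
                      prepare_case_slices(model_config, cases[[id]]))
  if (!length(train_slices)) stop("no training slices with support")
  val_prep <- lapply(splits$val, function(id)
    list(volume = preprocess(cases[[id]]),
         slices = prepare_case_slices(model_config, cases[[id]])))
  names(val_prep) <- splits$val
  model <- gfcn_init(model_config)
  opt <- adam_init(model$params)
  set.seed(tc$seed)
  history <- NULL
  best <- list(dcs = -Inf, epoch = 0L, params = model$params,
               state = model$state)
  wait <- 0L
  for (epoch in seq_len(tc$epochs)) {
    lr <- tc$lr
    if (tc$mode == "comparison" && epoch > tc$lr_decay_epoch)
      lr <- lr * tc$lr_decay_factor
    ord <- sample(length(train_slices))
    batches <- split(ord, ceiling(seq_along(ord) / tc$batch_size))
    if (!is.null(tc$steps_per_epoch))
      batches <- batches[seq_len(min(length(batches),
                                     tc$steps_per_epoch))]
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      bat <- gfcn_batch(train_slices[batches[[bi]]])
      trace <- gfcn_forward(model, bat, train = TRUE)
      loss <- soft_dice_loss(trace$prob, bat$y, tc$smooth)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch, ", step ", bi,
             " (loss = ", loss, "); the run is unstable -- lower the ",
             "learning rate or switch pooling operators")
      dprob <- soft_dice_grad(trace$prob, bat$y, tc$smooth)
      dscore0 <- dprob * trace$prob * (1 - trace$prob)
      grads <- gfcn_backward(model, trace, dscore0)
      st <- adam_step(model$params, grads, opt, lr)
      model$params <- st$params
      opt <- st$opt
      model$state <- trace$state
      losses[bi] <- loss
    }
    vrow <- validate_epoch(model, val_prep, tc)
    history <- rbind(history,
                     cbind(data.frame(epoch = epoch,
                                      loss = mean(losses), lr = lr),
                           vrow))
    if (tc$verbose)
      message(sprintf(
        "epoch %3d  loss %.4f  val DCS (slice) %.4f  (volume) %.4f",
        epoch, mean(losses), vrow$val_dcs_sample, vrow$val_dcs_volume))
    if (is.finite(vrow$val_dcs_volume) &&
        vrow$val_dcs_volume > best$dcs) {
      best <- list(dcs = vrow$val_dcs_volume, epoch = epoch,
                   params = model$params, state = model$state)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tc$patience) break
    }
  }
  best_model <- model
  best_model$params <- best$params
  best_model$state <- best$state
  structure(list(model = best_model, last_model = model,
                 history = history, best_epoch = best$epoch,
                 model_config = model_config, train_config = tc),
            class = "gfcn_fit")
}

validate_epoch <- function(model, val_prep, tc) {
  if (!length(val_prep))
    return(data.frame(val_dcs_sample = NA_real_,
                      val_dcs_volume = NA_real_, val_hd_volume = NA_real_,
                      val_recall_volume = NA_real_,
                      val_precision_volume = NA_real_,
                      val_cod_volume = NA_real_))
  ev <- evaluate_cases(model, val_prep, tc$threshold)
  data.frame(val_dcs_sample = ev$sample$summary[["dcs"]],
             val_dcs_volume = ev$volume$summary[["dcs"]],
             val_hd_volume = ev$volume$summary[["hd"]],
             val_recall_volume = ev$volume$summary[["recall"]],
             val_precision_volume = ev$volume$summary[["precision"]],
             val_cod_volume = ev$volume$summary[["cod"]])
}

# Forward every prepared slice of a case in evaluation mode and assemble
# probability / mask volumes.
predict_case <- function(model, prep, threshold = 0.5) {
  vol <- prep$volume
  d <- dim(vol$channels)
  prob <- array(0, d[-1])
  for (sl in prep$slices) {
    trace <- gfcn_forward(model, sl, train = FALSE)
    prob[sl$slice_meta$slice_index, , ] <-
      graph_to_slice(sl$graph, trace$prob)
  }
  list(prob = prob, mask = (prob >= threshold) * 1)
}

evaluate_cases <- function(model, preps, threshold = 0.5) {
  vol_rows <- NULL
  slice_rows <- NULL
  for (id in names(preps)) {
    prep <- preps[[id]]
    pc <- predict_case(model, prep, threshold)
    vr <- metrics_row(pc$mask, prep$volume$mask, prep$volume$spacing,
                      pred_prob = pc$prob)
    vr$case <- id
    vol_rows <- rbind(vol_rows, vr)
    for (sl in prep$slices) {
      s <- sl$slice_meta$slice_index
      sr <- metrics_row(pc$mask[s, , ], prep$volume$mask[s, , ],
                        prep$volume$spacing[-1],
                        pred_prob = pc$prob[s, , ])
      sr$case <- id
      sr$slice <- s
      slice_rows <- rbind(slice_rows, sr)
    }
  }
  list(volume = aggregate_metrics(vol_rows, "volume_wise"),
       sample = aggregate_metrics(slice_rows, "sample_wise"))
}

#' Evaluate a model on cases, volume-wise and sample-wise
#'
#' Runs slice-wise forward passes in evaluation mode, stacks the per-slice
#' probabilities into case volumes, thresholds them, and computes the full
#' metric set per case (volume-wise, with lesion-size strata) and per
#' slice (sample-wise).
#'
#' @param model a `gfcn_model` or `gfcn_fit` (its best checkpoint is
#'   used).
#' @param cases named list of [case_volume()] objects.
#' @param case_ids which cases to evaluate (default all).
#' @param threshold probability threshold (default 0.5).
#' @return List with `volume` and `sample` [aggregate_metrics()] reports
#'   and `predictions` (per-case probability and mask volumes).
#' @export
gfcn_evaluate <- function(model, cases, case_ids = names(cases),
                          threshold = 0.5) {
  if (inherits(model, "gfcn_fit")) model <- model$model
  preps <- lapply(cases[case_ids], function(v)
    list(volume = preprocess(v),
         slices = prepare_case_slices(model$config, v)))
  names(preps) <- case_ids
  ev <- evaluate_cases(model, preps, threshold)
  ev$predictions <- lapply(preps, function(p)
    predict_case(model, p, threshold))
  ev
}

#' Fourfold cross-validation
#'
#' Partitions the cases into `tc$folds` folds (seeded).  Per fold, the
#' held-out fold is the test set and the remaining cases are split 9:1
#' into training and validation; the best validation checkpoint is
#' evaluated volume-wise on the test fold.  Fold summaries are pooled as
#' unweighted means with variances across folds.
#'
#' @inheritParams gfcn_train
#' @return An object of class `gfcn_cv`: list with `folds` (per-fold fits
#'   and volume-wise reports), `summary` (pooled mean per metric),
#'   `variance`, and `per_case` rows usable for paired tests.
#' @export
gfcn_crossvalidate <- function(model_config, tc, cases) {
  ids <- names(cases)
  set.seed(tc$seed)
  perm <- sample(ids)
  assignment <- split(perm, rep(seq_len(tc$folds),
                                times = largest_remainder(
                                  length(ids),
                                  rep(1, tc$folds))))
  folds <- list()
  per_case <- NULL
  for (f in seq_len(tc$folds)) {
    test_ids <- assignment[[f]]
    rest <- setdiff(perm, test_ids)
    nv <- max(1L, round(length(rest) / 10))
    val_ids <- rest[seq_len(nv)]
    train_ids <- setdiff(rest, val_ids)
    fit <- gfcn_train(model_config, tc, cases,
                      list(train = train_ids, val = val_ids))
    ev <- gfcn_evaluate(fit, cases, test_ids, tc$threshold)
    rows <- ev$volume$rows
    rows$fold <- f
    per_case <- rbind(per_case, rows)
    folds[[f]] <- list(fit = fit, report = ev$volume,
                       test_ids = test_ids)
  }
  fold_means <- t(vapply(folds, function(fd) fd$report$summary,
                         numeric(length(METRIC_COLS))))
  structure(list(folds = folds, summary = colMeans(fold_means),
                 variance = apply(fold_means, 2, stats::var),
                 per_case = per_case),
            class = "gfcn_cv")
}

#' Paired comparison of two evaluations
#'
#' Two-sided paired t-test on a per-case metric from two volume-wise
#' reports covering the same cases (e.g. two unpooling methods on
#' identical folds).
#'
#' @param rows_a,rows_b `rows` data frames from volume-wise
#'   [aggregate_metrics()] reports with matching `case` columns.
#' @param metric metric column name (default `"dcs"`).
#' @return The `htest` object from [stats::t.test()].
#' @export
paired_metric_test <- function(rows_a, rows_b, metric = "dcs") {
  m <- match(rows_a$case, rows_b$case)
  if (anyNA(m)) stop("reports do not cover the same cases")
  stats::t.test(rows_a[[metric]], rows_b[[metric]][m], paired = TRUE)
}

#' Save / load a fitted model
#'
#' Checkpoints serialize the parameters, batch-norm state, model config and
#' training config with `saveRDS`.
#'
#' @param fit a `gfcn_fit` or `gfcn_model`.
#' @param path file path.
#' @return `gfcn_load` returns the restored object.
#' @export
gfcn_save <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname gfcn_save
#' @export
gfcn_load <- function(path) readRDS(path)
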