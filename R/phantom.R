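#' Pseudo-CTP phantom specification
#'
#' Parameters of the synthetic multi-modal phantom generator.  Each case has
#' a brain-shaped support region (a superellipsoid occupying roughly 60% of
#' the grid), constant per-modality baselines inside the brain, and a lesion
#' built from 1-3 anisotropic blobs whose total size is drawn log-uniformly
#' from `lesion_size_range` (a long-tailed distribution spanning small,
#' medium and large lesions).  Inside the lesion the perfusion channels are
#' scaled by the stroke-physiology contrast multipliers (CBF and CBV
#' depressed, MTT and Tmax elevated) and the CT is mildly hypo-intense;
#' i.i.d. Gaussian noise is added inside the brain and values are clipped
#' at 0, so voxels outside the brain stay exactly 0.
#'
#' @param shape integer 3-vector `(depth, height, width)`.
#' @param n_cases number of cases for [make_dataset()].
#' @param lesion_size_range lesion size as a fraction of brain voxels,
#'   drawn log-uniformly from this interval.
#' @param contrast named multipliers applied inside the lesion to the
#'   perfusion channels.
#' @param ct_lesion CT multiplier inside the lesion.
#' @param noise_sigma Gaussian noise scale, relative to each channel's
#'   baseline.
#' @param lesion_free_slice_prob fraction of slices kept clear of lesion
#'   (the lesion is confined to a central slab of `1 - p` of the depth), so
#'   slice-wise processing sees empty masks as in real data.
#' @param spacing voxel size in mm.
#' @param seed integer master seed; with the case index it fully determines
#'   each volume.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(8L, 64L, 64L), n_cases = 20L,
                         lesion_size_range = c(0.005, 0.15),
                         contrast = c(cbf = 0.3, cbv = 0.4, mtt = 2.5,
                                      tmax = 3.0),
                         ct_lesion = 0.9, noise_sigma = 0.05,
                         lesion_free_slice_prob = 0.25,
                         spacing = c(5, 1, 1), seed = 1L) {
  if (any(contrast <= 0)) stop("contrast multipliers must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (any(lesion_size_range <= 0) || any(lesion_size_range >= 1))
    stop("lesion volume fraction must lie in (0,1)")
  if (lesion_free_slice_prob < 0 || lesion_free_slice_prob >= 1)
    stop("lesion_free_slice_prob must be in [0,1)")
  structure(list(shape = as.integer(shape), n_cases = as.integer(n_cases),
                 lesion_size_range = lesion_size_range,
                 contrast = contrast, ct_lesion = ct_lesion,
                 noise_sigma = noise_sigma,
                 lesion_free_slice_prob = lesion_free_slice_prob,
                 spacing = spacing, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Typical in-brain baseline values per modality (HU, ml/100g/min, ml/100g,
# s, s); only their relative scale matters after min-max normalization.
PHANTOM_BASELINE <- c(ct = 40, cbf = 50, cbv = 4, mtt = 4, tmax = 2)

phantom_grids <- function(shape) {
  list(z = array(rep(seq_len(shape[1]), times = shape[2] * shape[3]),
                 shape),
       r = array(rep(rep(seq_len(shape[2]), each = shape[1]),
                     times = shape[3]), shape),
       c = array(rep(seq_len(shape[3]), each = shape[1] * shape[2]),
                 shape))
}

phantom_brain <- function(shape) {
  g <- phantom_grids(shape)
  ctr <- (shape + 1) / 2
  semi <- shape / 2 * 0.98
  u <- abs(g$z - ctr[1]) / semi[1]
  v <- abs(g$r - ctr[2]) / semi[2]
  w <- abs(g$c - ctr[3]) / semi[3]
  (u^2.5 + v^2.5 + w^2.5) <= 1
}

case_seed <- function(seed, case_index) {
  as.integer((abs(seed) * 7919 + case_index * 104729) %% 2147483629)
}

#' Generate one phantom case
#'
#' Deterministic given `(spec$seed, case_index)`.
#'
#' @param spec a [phantom_spec()].
#' @param case_index positive integer.
#' @return A [case_volume()] with a nonempty lesion mask.
#' @export
make_case <- function(spec, case_index) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(case_seed(spec$seed, case_index))
  shape <- spec$shape
  brain <- phantom_brain(shape)
  n_brain <- sum(brain)
  g <- phantom_grids(shape)
  lo <- log(spec$lesion_size_range[1]); hi <- log(spec$lesion_size_range[2])
  frac <- exp(stats::runif(1, lo, hi))
  # lesion centers confined to a central slab so top/bottom slices stay
  # lesion-free
  slab <- max(1, shape[1] * (1 - spec$lesion_free_slice_prob))
  zlo <- (shape[1] - slab) / 2 + 1
  zhi <- shape[1] - (shape[1] - slab) / 2
  lesion <- NULL
  target <- frac * n_brain
  for (attempt in 1:30) {
    n_balls <- sample(1:3, 1)
    share <- stats::runif(n_balls, 0.2, 1)
    share <- share / sum(share)
    grow <- 1 + 0.15 * (attempt - 1)   # widen slowly if placement fails
    les <- array(FALSE, shape)
    for (k in seq_len(n_balls)) {
      r0 <- grow * (3 * share[k] * target / (4 * pi))^(1 / 3)
      ctr <- c(stats::runif(1, zlo, zhi),
               stats::runif(1, 0.3 * shape[2], 0.7 * shape[2]),
               stats::runif(1, 0.3 * shape[3], 0.7 * shape[3]))
      ax <- pmax(r0 * stats::runif(3, 0.7, 1.4), 0.8)
      d <- ((g$z - ctr[1]) / ax[1])^2 + ((g$r - ctr[2]) / ax[2])^2 +
        ((g$c - ctr[3]) / ax[3])^2
      les <- les | d <= 1
    }
    les <- les & brain
    if (sum(les) >= max(2, 0.1 * target)) { lesion <- les; break }
  }
  if (is.null(lesion))
    stop("could not place a lesion inside the brain support")
  channels <- array(0, c(5L, shape))
  mult <- c(spec$ct_lesion, spec$contrast[c("cbf", "cbv", "mtt", "tmax")])
  for (i in 1:5) {
    base <- PHANTOM_BASELINE[i]
    vol <- array(0, shape)
    vol[brain] <- base
    vol[lesion] <- base * mult[i]
    if (spec$noise_sigma > 0) {
      noise <- array(0, shape)
      noise[brain] <- stats::rnorm(n_brain, 0,
                                   spec$noise_sigma * base)
      vol <- vol + noise
    }
    vol[vol < 0] <- 0
    vol[!brain] <- 0
    channels[i, , , ] <- vol
  }
  case_volume(channels, array(as.numeric(lesion), shape), spec$spacing,
              sprintf("phantom_%03d", case_index))
}

# Largest-remainder apportionment of n into length(ratios) parts.
largest_remainder <- function(n, ratios) {
  quota <- n * ratios / sum(ratios)
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    o <- order(-(quota - base))
    base[o[seq_len(left)]] <- base[o[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Generate a phantom dataset with train/validation/test splits
#'
#' Generates `spec$n_cases` phantom cases, assigns them to splits by
#' seeded shuffling with largest-remainder rounding of the split ratios,
#' and optionally writes each case as NIfTI files plus a CSV manifest.
#'
#' @param spec a [phantom_spec()].
#' @param split_ratios numeric 3-vector (train, val, test) summing to 1
#'   (any positive weights are normalized).
#' @param out_dir if non-`NULL`, cases and `manifest.csv` are written
#'   there.
#' @return List with `cases` (named list of [case_volume()]), `manifest`
#'   (data frame with `case_id`, `split`, `lesion_voxels`), and `splits`
#'   (named list of case-id character vectors).
#' @export
make_dataset <- function(spec, split_ratios = c(0.7, 0.1, 0.2),
                         out_dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  sizes <- largest_remainder(spec$n_cases, split_ratios)
  if (any(sizes < 0) || sum(sizes) != spec$n_cases)
    stop("invalid split sizes for n_cases = ", spec$n_cases)
  cases <- lapply(seq_len(spec$n_cases), function(i) make_case(spec, i))
  names(cases) <- vapply(cases, `[[`, character(1), "case_id")
  set.seed(case_seed(spec$seed, 0L))
  perm <- sample(spec$n_cases)
  split <- rep(c("train", "val", "test"), times = sizes)
  split_of <- character(spec$n_cases)
  split_of[perm] <- split
  manifest <- data.frame(
    case_id = names(cases), split = split_of,
    lesion_voxels = vapply(cases, function(v) sum(v$mask), numeric(1)),
    row.names = NULL)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- lapply(cases, write_case, dir = out_dir)
    for (ch in c(CHANNEL_ORDER, "mask"))
      manifest[[paste0("path_", ch)]] <-
        vapply(paths, `[[`, character(1), ch)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  splits <- split(manifest$case_id, manifest$split)
  list(cases = cases, manifest = manifest,
       splits = splits[intersect(c("train", "val", "test"),
                                 names(splits))])
}

#' Load a dataset written by [make_dataset()] from its manifest
#'
#' @param manifest_path path to `manifest.csv`.
#' @return Same structure as [make_dataset()].
#' @export
read_dataset <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path)
  cases <- lapply(seq_len(nrow(manifest)), function(i) {
    paths <- as.list(manifest[i, paste0("path_",
                                        c(CHANNEL_ORDER, "mask"))])
    names(paths) <- c(CHANNEL_ORDER, "mask")
    read_case(paths, case_id = manifest$case_id[i])
  })
  names(cases) <- manifest$case_id
  splits <- split(manifest$case_id, manifest$split)
  list(cases = cases, manifest = manifest,
       splits = splits[intersect(c("train", "val", "test"),
                                 names(splits))])
}
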