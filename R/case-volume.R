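CHANNEL_ORDER <- c("ct", "cbf", "cbv", "mtt", "tmax")

#' Multi-modal CT perfusion case volume
#'
#' A `case_volume` bundles the five co-registered input channels
#' (non-contrast CT plus the four perfusion parameter maps CBF, CBV, MTT,
#' Tmax), the binary lesion mask, and the voxel spacing for one case.
#' The first array axis is the slice axis: `channels` has dimension
#' `(5, depth, height, width)` and `mask` has `(depth, height, width)`.
#'
#' @param channels numeric array `(5, depth, height, width)`; channel order
#'   CT, CBF, CBV, MTT, Tmax.
#' @param mask binary array `(depth, height, width)`.
#' @param spacing numeric length-3 voxel size in mm per axis (slice, row,
#'   column).
#' @param case_id character identifier.
#' @return An object of class `case_volume`.
#' @export
case_volume <- function(channels, mask, spacing = c(1, 1, 1),
                        case_id = "case") {
  channels <- as.array(channels)
  mask <- as.array(mask)
  if (length(dim(channels)) != 4L || dim(channels)[1] != 5L)
    stop("`channels` must be a (5, depth, height, width) array")
  if (!identical(dim(channels)[-1], dim(mask)))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match channel shape ",
         paste(dim(channels)[-1], collapse = "x"))
  check_binary(mask, "mask")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes")
  structure(list(channels = channels, mask = round(mask),
                 spacing = as.numeric(spacing),
                 case_id = as.character(case_id)),
            class = "case_volume")
}

check_binary <- function(x, what, tol = 1e-6) {
  r <- round(x)
  if (any(abs(x - r) > tol) || any(!(r %in% c(0, 1))))
    stop("`", what, "` is not binary: values outside {0,1}")
  invisible(TRUE)
}

#' @export
print.case_volume <- function(x, ...) {
  d <- dim(x$channels)
  cat("case_volume ", x$case_id, ": ", d[1], " channels, ",
      paste(d[-1], collapse = " x "), " voxels, spacing ",
      paste(signif(x$spacing, 3), collapse = "/"), " mm\n", sep = "")
  invisible(x)
}

#' Read one case from NIfTI files
#'
#' Reads the five channel volumes and the lesion mask and stacks them into a
#' [case_volume()] in the fixed channel order CT, CBF, CBV, MTT, Tmax.
#' All six volumes must share one spatial shape; the mask must be binary.
#'
#' @param paths named list or character vector with elements `ct`, `cbf`,
#'   `cbv`, `mtt`, `tmax`, `mask` giving NIfTI (.nii/.nii.gz) file paths.
#' @param case_id identifier; defaults to the mask file name stem.
#' @return A [case_volume()].
#' @export
read_case <- function(paths, case_id = NULL) {
  paths <- as.list(paths)
  need <- c(CHANNEL_ORDER, "mask")
  missing_keys <- setdiff(need, names(paths))
  if (length(missing_keys))
    stop("missing paths for: ", paste(missing_keys, collapse = ", "))
  for (k in need)
    if (!file.exists(paths[[k]]))
      stop("file not found: ", paths[[k]])
  imgs <- lapply(paths[need], function(p) RNifti::readNifti(p))
  dims <- lapply(imgs, dim)
  ref <- dims[[1]]
  for (k in seq_along(dims))
    if (!identical(dims[[k]], ref))
      stop("shape mismatch: ", need[k], " is ",
           paste(dims[[k]], collapse = "x"), ", expected ",
           paste(ref, collapse = "x"))
  mask <- array(as.numeric(imgs$mask), ref)
  check_binary(mask, "mask")
  channels <- array(0, dim = c(5L, ref))
  for (i in seq_along(CHANNEL_ORDER))
    channels[i, , , ] <- as.array(imgs[[CHANNEL_ORDER[i]]])
  sp <- RNifti::pixdim(imgs$mask)[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  if (is.null(case_id))
    case_id <- sub("\\.nii(\\.gz)?$", "", basename(paths$mask))
  case_volume(channels, mask, sp, case_id)
}

#' Write one case to NIfTI files
#'
#' Writes the five channels and mask as `<case_id>_<channel>.nii.gz` under
#' `dir` (float32 for channels, uint8 for the mask) plus a sidecar JSON
#' recording channel order and spacing.
#'
#' @param volume a [case_volume()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_case <- function(volume, dir) {
  stopifnot(inherits(volume, "case_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (i in seq_along(CHANNEL_ORDER)) {
    p <- file.path(dir, paste0(volume$case_id, "_", CHANNEL_ORDER[i],
                               ".nii.gz"))
    arr <- volume$channels[i, , , ]
    attr(arr, "pixdim") <- volume$spacing
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), p)
    files[CHANNEL_ORDER[i]] <- p
  }
  p <- file.path(dir, paste0(volume$case_id, "_mask.nii.gz"))
  arr <- array(as.integer(volume$mask), dim(volume$mask))
  attr(arr, "pixdim") <- volume$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), p)
  files["mask"] <- p
  sidecar <- file.path(dir, paste0(volume$case_id, "_channels.json"))
  jsonlite::write_json(list(case_id = volume$case_id,
                            channel_order = CHANNEL_ORDER,
                            spacing = volume$spacing),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' Preprocess a case volume
#'
#' Applies the two preprocessing steps used throughout the package:
#' (a) the CT channel is zeroed wherever the voxelwise sum of the four
#' perfusion channels is zero, restricting the CT to the brain support; and
#' (b) each channel is min-max rescaled over the whole volume to `[0,1]`
#' (a constant channel maps to all zeros).
#'
#' @param volume a [case_volume()].
#' @return The preprocessed [case_volume()], with attribute
#'   `preprocessed = TRUE`.
#' @export
preprocess <- function(volume) {
  stopifnot(inherits(volume, "case_volume"))
  ch <- volume$channels
  ctp_sum <- ch[2, , , ] + ch[3, , , ] + ch[4, , , ] + ch[5, , , ]
  ct <- ch[1, , , ]
  ct[ctp_sum == 0] <- 0
  ch[1, , , ] <- ct
  for (i in 1:5) {
    x <- ch[i, , , ]
    lo <- min(x); hi <- max(x)
    ch[i, , , ] <- if (hi > lo) (x - lo) / (hi - lo) else 0 * x
  }
  out <- volume
  out$channels <- ch
  attr(out, "preprocessed") <- TRUE
  out
}

#' Brain-support mask of a slice
#'
#' Pixels where the sum of the four perfusion channels is nonzero; the
#' node support used for graph construction in `brain` mode.
#'
#' @param volume a [case_volume()].
#' @param slice_index slice along the first axis.
#' @return Logical `(height, width)` matrix.
#' @export
slice_support <- function(volume, slice_index) {
  ch <- volume$channels
  s <- ch[2, slice_index, , ] + ch[3, slice_index, , ] +
    ch[4, slice_index, , ] + ch[5, slice_index, , ]
  s != 0
}
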