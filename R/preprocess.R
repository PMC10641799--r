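# B-scan preprocessing chain: macular slice selection, interval sampling,
# center crop, binarization, morphological dilation, largest-contour
# foreground extraction, resize, and 3D volume assembly. No randomness
# anywhere in this module.

#' Preprocessing configuration
#'
#' Defaults implement the macular pipeline for 400-slice, 400 x 640 stacks:
#' slices `[130, 270)` (140 B-scans) sampled at stride 2 down to 70, middle
#' 140 columns kept, each foreground-extracted slice resized to 100 x 100,
#' yielding a 100 x 100 x 70 volume.
#'
#' @param slice_lo,slice_hi half-open 0-based slice range `[slice_lo, slice_hi)`
#' @param sample_stride keep every `sample_stride`-th selected slice
#' @param crop_width width of the centered horizontal crop, in pixels
#' @param dilation_kernel diameter of the elliptical structuring element (odd)
#' @param dilation_iters number of dilation passes
#' @param out_xy in-plane output size after resize
#' @param out_depth expected number of slices after sampling
#' @param binarize_method `"otsu"` (data-driven threshold) or `"fixed"`
#' @param fixed_threshold intensity threshold used by `"fixed"` and as the
#'   fallback when Otsu is undefined (constant slice)
#' @return a `preprocess_config` list
#' @export
preprocess_config <- function(slice_lo = 130L, slice_hi = 270L,
                              sample_stride = 2L, crop_width = 140L,
                              dilation_kernel = 5L, dilation_iters = 2L,
                              out_xy = 100L, out_depth = 70L,
                              binarize_method = c("otsu", "fixed"),
                              fixed_threshold = 25) {
  binarize_method <- match.arg(binarize_method)
  if (slice_hi <= slice_lo) stop("slice_hi must exceed slice_lo")
  if (sample_stride < 1L) stop("sample_stride must be >= 1")
  if (dilation_kernel %% 2L != 1L) stop("dilation_kernel must be odd")
  n_sel <- slice_hi - slice_lo
  n_out <- length(seq.int(1L, n_sel, by = sample_stride))
  if (n_out != out_depth) {
    stop("slice range and stride yield ", n_out, " slices but out_depth is ",
         out_depth)
  }
  structure(list(slice_lo = as.integer(slice_lo), slice_hi = as.integer(slice_hi),
                 sample_stride = as.integer(sample_stride),
                 crop_width = as.integer(crop_width),
                 dilation_kernel = as.integer(dilation_kernel),
                 dilation_iters = as.integer(dilation_iters),
                 out_xy = as.integer(out_xy), out_depth = as.integer(out_depth),
                 binarize_method = binarize_method,
                 fixed_threshold = fixed_threshold),
            class = "preprocess_config")
}

#' Select the macular slice range and subsample it
#'
#' Keeps slices with 0-based indices in `[slice_lo, slice_hi)` — 140 under the
#' defaults — then every `sample_stride`-th of those (70 under the defaults).
#'
#' @param stack a `bscan_stack`
#' @param cfg a [preprocess_config()]
#' @param apply_stride if FALSE, return the full selected range unsampled
#' @return list of slice matrices
#' @export
select_slices <- function(stack, cfg = preprocess_config(),
                          apply_stride = TRUE) {
  n <- length(stack$slices)
  if (n < cfg$slice_hi) {
    stop("stack has ", n, " slices but the configuration requires at least ",
         cfg$slice_hi)
  }
  sel <- stack$slices[(cfg$slice_lo + 1L):cfg$slice_hi]
  if (apply_stride) sel <- sel[seq.int(1L, length(sel), by = cfg$sample_stride)]
  sel
}

#' Horizontally centered crop of a slice
#' @param slice matrix (height x width)
#' @param crop_width output width; left margin is `floor((W - crop_width)/2)`
#' @export
center_crop <- function(slice, crop_width) {
  W <- ncol(slice)
  if (crop_width > W) stop("crop_width ", crop_width, " exceeds slice width ", W)
  m <- (W - crop_width) %/% 2L
  slice[, (m + 1L):(m + crop_width), drop = FALSE]
}

#' Binarize a slice (foreground/background)
#'
#' Pixels with intensity `>=` the threshold become 1. The threshold is Otsu's
#' (computed on the 0-255 histogram) or the fixed value per the configuration;
#' a constant slice has no Otsu threshold and falls back to the fixed value.
#'
#' @param slice matrix with intensities in 0-255
#' @param cfg a [preprocess_config()]
#' @return integer matrix in {0, 1}
#' @export
binarize_slice <- function(slice, cfg = preprocess_config()) {
  stopifnot(length(slice) > 0)
  thr <- if (cfg$binarize_method == "fixed" || diff(range(slice)) == 0) {
    if (cfg$binarize_method == "otsu") {
      octlan_log("binarize_slice: constant slice, falling back to fixed threshold")
    }
    cfg$fixed_threshold
  } else {
    255 * EBImage::otsu(EBImage::Image(slice / 255), range = c(0, 1))
  }
  m <- (slice >= thr) * 1L
  storage.mode(m) <- "integer"
  m
}

#' Morphological dilation with an elliptical structuring element
#' @param mask binary matrix
#' @param cfg a [preprocess_config()]; `dilation_kernel` px disc applied
#'   `dilation_iters` times
#' @return binary matrix (superset of the input)
#' @export
dilate_mask <- function(mask, cfg = preprocess_config()) {
  brush <- EBImage::makeBrush(cfg$dilation_kernel, shape = "disc")
  out <- mask
  for (i in seq_len(cfg$dilation_iters)) out <- EBImage::dilate(out, brush)
  m <- (out > 0) * 1L
  storage.mode(m) <- "integer"
  m
}

#' Keep the largest contour's filled region of the mask and apply it
#'
#' Labels the connected components of the dilated mask, keeps the
#' largest-area component, fills its contour (holes included), and zeroes the
#' slice outside that region. An empty mask returns the slice unchanged with
#' a warning (degenerate-input fallback).
#'
#' @param slice intensity matrix
#' @param dilated_mask binary matrix of the same shape
#' @return masked intensity matrix
#' @export
extract_foreground <- function(slice, dilated_mask) {
  stopifnot(all(dim(slice) == dim(dilated_mask)))
  if (sum(dilated_mask) == 0) {
    warning("extract_foreground: empty mask; returning slice unchanged")
    return(slice)
  }
  lab <- EBImage::bwlabel(dilated_mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which.max(areas)
  region <- EBImage::fillHull((lab == keep) * 1L)
  slice * (region > 0)
}

# single-slice pipeline after selection: crop -> binarize -> dilate ->
# extract -> resize -> [0,1]
preprocess_slice <- function(slice, cfg) {
  cr <- center_crop(slice, cfg$crop_width)
  bm <- binarize_slice(cr, cfg)
  dm <- dilate_mask(bm, cfg)
  fg <- extract_foreground(cr, dm)
  rs <- EBImage::resize(EBImage::Image(fg / 255), w = cfg$out_xy, h = cfg$out_xy)
  pmin(pmax(as.matrix(EBImage::imageData(rs)), 0), 1)
}

#' Assemble a preprocessed 3D volume from a B-scan stack
#'
#' Runs selection, sampling, crop, binarization, dilation, foreground
#' extraction and bilinear resize per slice, rescales intensities to `[0, 1]`,
#' and stacks the slices along depth. Deterministic.
#'
#' @param stack a `bscan_stack`
#' @param cfg a [preprocess_config()]
#' @return an `oct_volume`: list with `data`
#'   (`out_xy` x `out_xy` x `out_depth` array in `[0,1]`), `patient_id`,
#'   `eye_id`, `label`
#' @export
assemble_volume <- function(stack, cfg = preprocess_config()) {
  sel <- select_slices(stack, cfg)
  vol <- array(0, c(cfg$out_xy, cfg$out_xy, cfg$out_depth))
  for (i in seq_along(sel)) {
    vol[, , i] <- tryCatch(preprocess_slice(sel[[i]], cfg),
                           error = function(e) {
                             stop("preprocessing failed at sampled slice ", i,
                                  ": ", conditionMessage(e))
                           })
  }
  structure(list(data = vol, patient_id = stack$patient_id,
                 eye_id = stack$eye_id, label = stack$label),
            class = "oct_volume")
}

#' Preprocess a list of stacks into volumes, optionally writing them to disk
#'
#' @param stacks list of `bscan_stack`
#' @param cfg a [preprocess_config()]
#' @param out_dir optional directory; volumes are written as serialized array
#'   files (one per eye) plus a `manifest.tsv` (patient_id, eye_id, label,
#'   path)
#' @return list of `oct_volume`
#' @export
preprocess_dataset <- function(stacks, cfg = preprocess_config(),
                               out_dir = NULL) {
  vols <- lapply(stacks, assemble_volume, cfg = cfg)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- vapply(vols, function(v) {
      p <- file.path(out_dir, paste0(v$eye_id, ".rds"))
      saveRDS(v, p)
      p
    }, "")
    man <- data.frame(patient_id = vapply(vols, `[[`, "", "patient_id"),
                      eye_id = vapply(vols, `[[`, "", "eye_id"),
                      label = vapply(vols, `[[`, 0L, "label"),
                      path = paths)
    utils::write.table(man, file.path(out_dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  vols
}
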