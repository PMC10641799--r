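# Grad-CAM for the 3D backbone, and binarization of the localization map into
# an auxiliary lesion mask.
#
# Channel weights are the spatially pooled gradients of the class score with
# respect to the tap-layer activations,
#     alpha_k = (1/Z) sum_over_positions d y_c / d A_k,
# with Z the product of the tap layer's spatial extents (the 2D formulation
# pools over width and height; for a 3D network the pool runs over all three
# spatial axes). The localization map is ReLU(sum_k alpha_k A_k).

#' Grad-CAM localization map for one volume
#'
#' @param model model handle (typically the stage-1 trained backbone)
#' @param volume `oct_volume` or 3D array
#' @param class_label class driving the map: 0 (DR) or 1 (DN)
#' @param layer_name tap layer, e.g. `"stage2"`; default: last stage
#' @param mask optional lesion mask if `model` carries attention sites
#' @return a `cam_map`: list with `values` (nonnegative 3D array at the tap
#'   layer's spatial resolution), `alpha` (channel weights), `Z`,
#'   `class_label`, `layer_name`
#' @export
gradcam <- function(model, volume, class_label, layer_name = NULL,
                    mask = NULL) {
  if (is.null(layer_name)) layer_name <- paste0("stage", model$cfg$n_stages)
  cls <- as.integer(class_label)
  if (cls < 0L || cls >= model$cfg$n_classes) {
    stop("class_label must be in 0..", model$cfg$n_classes - 1L)
  }
  fw <- net_forward(model, volume, mask = mask, keep_cache = TRUE)
  dscores <- rep(0, model$cfg$n_classes)
  dscores[cls + 1L] <- 1
  bw <- net_backward(model, fw$cache, dscores, tap_grads = layer_name)
  A <- fw$taps[[layer_name]]
  if (is.null(A)) stop("unknown tap layer: ", layer_name)
  grad <- bw$tap_grads[[layer_name]]
  Z <- nrow(A$v)
  alpha <- colMeans(grad)              # (1/Z) * spatial sum of d y_c / d A_k
  L <- pmax(as.vector(A$v %*% alpha), 0)
  structure(list(values = array(L, A$d), alpha = alpha, Z = Z,
                 class_label = cls, layer_name = layer_name),
            class = "cam_map")
}

# Red channel of the jet colormap as a function of normalized intensity in
# [0,1]; optional emulation of thresholding a rendered heatmap's R channel.
jet_red <- function(v) pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)

#' Binarize a Grad-CAM map into a lesion mask at volume resolution
#'
#' Min-max normalizes the map to `[0, 255]`, upsamples it trilinearly to the
#' volume grid, and thresholds: voxels with value `>= T` become 1, the rest 0.
#' A constant map (no spatial discrimination) yields an all-ones mask so that
#' downstream attention degrades to plain self-attention.
#'
#' @param cam a `cam_map` from [gradcam()]
#' @param volume_shape integer vector c(H, W, D) of the target grid
#' @param T threshold on the 0–255 scale (default 50)
#' @param emulate_heatmap_r if TRUE, pass the normalized map through the red
#'   channel of the jet colormap before thresholding (emulates binarizing a
#'   rendered heatmap rather than the raw map)
#' @return a `lesion_mask`: list with `values` (3D {0,1} array), `threshold`,
#'   `source`
#' @export
cam_to_mask <- function(cam, volume_shape, T = 50, emulate_heatmap_r = FALSE) {
  stopifnot(inherits(cam, "cam_map"), T >= 0, T <= 255)
  v <- cam$values
  rng <- range(v)
  if (rng[2] - rng[1] <= .Machine$double.eps) {
    octlan_log("cam_to_mask: constant localization map; returning all-ones mask")
    return(structure(list(values = array(1, volume_shape), threshold = T,
                          source = "constant_fallback"),
                     class = "lesion_mask"))
  }
  vn <- (v - rng[1]) / (rng[2] - rng[1])
  if (emulate_heatmap_r) vn <- jet_red(vn)
  up <- resize_trilinear(vn * 255, volume_shape)
  structure(list(values = array(as.numeric(up >= T), volume_shape),
                 threshold = T, source = "gradcam"),
            class = "lesion_mask")
}

#' Generate lesion masks for a set of volumes, with on-disk caching
#'
#' One Grad-CAM pass per volume through `model`, binarized by [cam_to_mask()].
#' Masks are cached under `cache_dir` keyed by (model parameter checksum,
#' eye id, threshold, label policy, tap layer); a rerun with identical inputs
#' reuses the cached files byte for byte.
#'
#' @param model stage-1 trained model handle
#' @param volumes list of `oct_volume`s (each with `eye_id` and, under the
#'   `true_label` policy, a `label`)
#' @param label_policy class driving each map: the volume's true label or the
#'   model's predicted class
#' @param T binarization threshold (0-255 scale)
#' @param layer_name tap layer; default last stage
#' @param cache_dir optional directory for the mask cache
#' @return named list `eye_id -> lesion_mask`
#' @export
batch_generate_masks <- function(model, volumes,
                                 label_policy = c("true_label", "predicted"),
                                 T = 50, layer_name = NULL, cache_dir = NULL) {
  label_policy <- match.arg(label_policy)
  if (is.null(layer_name)) layer_name <- paste0("stage", model$cfg$n_stages)
  ck <- if (!is.null(cache_dir)) model_checksum(model) else NULL
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }
  out <- list()
  for (vol in volumes) {
    eid <- vol$eye_id
    if (is.null(eid)) stop("every volume needs an eye_id")
    if (!is.null(cache_dir)) {
      side <- file.path(cache_dir, paste0(eid, ".json"))
      dat <- file.path(cache_dir, paste0(eid, ".rds"))
      if (file.exists(side) && file.exists(dat)) {
        meta <- jsonlite::read_json(side)
        if (identical(meta$checksum, ck) && meta$T == T &&
            identical(meta$policy, label_policy) &&
            identical(meta$layer, layer_name)) {
          out[[eid]] <- readRDS(dat)
          next
        }
      }
    }
    cls <- if (label_policy == "true_label") {
      if (is.null(vol$label)) stop("volume ", eid, " has no label (true_label policy)")
      vol$label
    } else {
      which.max(net_forward(model, vol)$scores) - 1L
    }
    cam <- gradcam(model, vol, cls, layer_name)
    msk <- cam_to_mask(cam, dim(vol$data), T = T)
    out[[eid]] <- msk
    if (!is.null(cache_dir)) {
      saveRDS(msk, dat)
      jsonlite::write_json(list(checksum = ck, T = T, policy = label_policy,
                                layer = layer_name),
                           side, auto_unbox = TRUE)
    }
  }
  out
}
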