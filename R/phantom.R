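# Synthetic OCT phantom generator.
#
# A phantom B-scan emulates a retinal cross-section: a dark background with a
# small number of smooth, bright, curved bands (retinal layers) spanning the
# image width, plus optional hyperreflective lesion blobs (a sphere in
# slice/x/y space) near the central slices and central columns, so the class
# signal survives the macular crop of the preprocessing chain. Geometry is
# drawn deterministically from the spec's seed; it is a shape phantom, not a
# speckle-physics simulation.

#' Specification of one synthetic B-scan stack
#'
#' @param width,height slice size in pixels (clinical export geometry:
#'   400 x 640)
#' @param n_slices number of B-scans per eye (clinical: 400)
#' @param n_layers number of bright retinal bands
#' @param lesion_present add a hyperreflective spherical lesion
#' @param lesion_center c(slice, x, y) voxel coordinate of the lesion center
#'   (0-based); NULL draws one inside the central region retained by the
#'   default macular crop
#' @param lesion_radius lesion sphere radius in pixels
#' @param noise_sigma additive Gaussian noise standard deviation (intensity
#'   units on the 0-255 scale)
#' @param background background intensity level
#' @param seed integer; identical specs (including seed) give bit-identical
#'   output
#' @return a `phantom_spec` list
#' @export
phantom_spec <- function(width = 400L, height = 640L, n_slices = 400L,
                         n_layers = 5L, lesion_present = FALSE,
                         lesion_center = NULL, lesion_radius = 15,
                         noise_sigma = 5, background = 10, seed = 1L) {
  if (width < 1L || height < 1L || n_slices < 1L) {
    stop("width, height and n_slices must be >= 1")
  }
  if (lesion_radius < 0) stop("lesion_radius must be >= 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_slices = as.integer(n_slices), n_layers = as.integer(n_layers),
                 lesion_present = isTRUE(lesion_present),
                 lesion_center = lesion_center,
                 lesion_radius = lesion_radius, noise_sigma = noise_sigma,
                 background = background, seed = as.integer(seed)),
            class = "phantom_spec")
}

# run fn with a private RNG stream, restoring the caller's stream
with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% 2147483647L)
  fn()
}

# Per-spec deterministic band geometry: center curve (quadratic in x, slow
# sinusoid in slice), thickness and intensity per layer.
phantom_geometry <- function(spec) {
  with_seed(spec$seed, function() {
    n <- spec$n_layers
    band_lo <- 0.35 * spec$height
    band_hi <- 0.65 * spec$height
    centers <- band_lo + (seq_len(n) - 0.5) / n * (band_hi - band_lo)
    list(center0 = centers,
         curve = stats::runif(n, 10, 40),            # quadratic sag in px
         tilt = stats::runif(n, -10, 10),
         thick = stats::runif(n, 0.012, 0.02) * spec$height,
         inten = stats::runif(n, 140, 220),
         slice_amp = stats::runif(1, 5, 15),         # smooth drift over slices
         slice_phase = stats::runif(1, 0, 2 * pi))
  })
}

default_lesion_center <- function(spec) {
  # inside the region retained by the default macular crop: central ~35% of
  # slices and columns, vertically inside the band region
  c(round(0.5 * spec$n_slices), round(0.5 * spec$width), round(0.5 * spec$height))
}

#' Generate one synthetic B-scan
#'
#' @param spec a [phantom_spec()]
#' @param slice_index 0-based slice index in `[0, n_slices)`
#' @return integer matrix (height x width) with values in 0-255
#' @export
generate_bscan <- function(spec, slice_index) {
  stopifnot(inherits(spec, "phantom_spec"))
  si <- as.integer(slice_index)
  if (si < 0L || si >= spec$n_slices) {
    stop("slice_index ", si, " out of range [0, ", spec$n_slices, ")")
  }
  geo <- phantom_geometry(spec)
  H <- spec$height; W <- spec$width
  img <- matrix(spec$background, H, W)
  xn <- (seq_len(W) - 1) / max(W - 1, 1) - 0.5       # [-0.5, 0.5]
  sdrift <- geo$slice_amp * sin(2 * pi * si / spec$n_slices + geo$slice_phase)
  rows <- seq_len(H)
  for (l in seq_len(spec$n_layers)) {
    cy <- geo$center0[l] + geo$curve[l] * (xn^2 * 4 - 0.5) +
      geo$tilt[l] * xn * 2 + sdrift
    half <- geo$thick[l] / 2
    on <- abs(outer(rows, cy, `-`)) <= half       # H x W band membership
    img[on] <- geo$inten[l]
  }
  if (spec$lesion_present) {
    ctr <- if (is.null(spec$lesion_center)) default_lesion_center(spec)
           else spec$lesion_center
    dz <- si - ctr[1]
    if (abs(dz) <= spec$lesion_radius) {
      r2 <- spec$lesion_radius^2 - dz^2
      yy <- rep(rows, W) - (ctr[3] + 1)
      xx <- rep(seq_len(W), each = H) - (ctr[2] + 1)
      inside <- (yy^2 + xx^2) <= r2
      img[inside] <- pmax(img[inside], 250)
    }
  }
  if (spec$noise_sigma > 0) {
    img <- with_seed(spec$seed * 1009L + si, function() {
      img + matrix(stats::rnorm(H * W, sd = spec$noise_sigma), H, W)
    })
  }
  m <- round(pmin(pmax(img, 0), 255))
  storage.mode(m) <- "integer"
  m
}

#' Generate a full B-scan stack for one eye
#'
#' @param spec a [phantom_spec()]
#' @param patient_id,eye_id identifiers
#' @param label class label: 0 (DR) or 1 (DN)
#' @return a `bscan_stack`: list with `slices` (list of matrices),
#'   `patient_id`, `eye_id`, `label`
#' @export
generate_stack <- function(spec, patient_id = "P001", eye_id = "P001_OD",
                           label = 0L) {
  slices <- lapply(seq_len(spec$n_slices) - 1L, function(i) generate_bscan(spec, i))
  structure(list(slices = slices, patient_id = patient_id, eye_id = eye_id,
                 label = as.integer(label), spec = spec),
            class = "bscan_stack")
}

#' Generate a labeled phantom dataset
#'
#' One stack per patient. DN-labeled stacks carry a hyperreflective lesion
#' inside the central-slice, central-column region (so the macular crop of the
#' preprocessing chain retains it); DR stacks have no lesion. The number of DN
#' labels is `round(n_patients * dn_fraction)`.
#'
#' @param n_patients number of patients (>= 1)
#' @param dn_fraction proportion of DN labels in `[0, 1]`
#' @param base_spec a [phantom_spec()] giving geometry, noise and lesion radius
#' @param seed integer seed controlling label assignment, lesion placement and
#'   per-patient band geometry
#' @return list of `bscan_stack`
#' @export
generate_dataset <- function(n_patients, dn_fraction, base_spec = phantom_spec(),
                             seed = 1L) {
  if (n_patients < 1L) stop("n_patients must be >= 1")
  if (dn_fraction < 0 || dn_fraction > 1) stop("dn_fraction must be in [0, 1]")
  n_dn <- round(n_patients * dn_fraction)
  with_seed(seed, function() {
    labels <- integer(n_patients)
    labels[sample.int(n_patients, n_dn)] <- 1L
    sp <- base_spec
    lapply(seq_len(n_patients), function(i) {
      pid <- sprintf("P%03d", i)
      pseed <- (seed * 6151L + i * 131L) %% 2147483647L
      ctr <- c(round(stats::runif(1, 0.375, 0.625) * sp$n_slices),
               round(stats::runif(1, 0.4, 0.6) * sp$width),
               round(stats::runif(1, 0.42, 0.58) * sp$height))
      spi <- phantom_spec(width = sp$width, height = sp$height,
                          n_slices = sp$n_slices, n_layers = sp$n_layers,
                          lesion_present = labels[i] == 1L,
                          lesion_center = ctr,
                          lesion_radius = sp$lesion_radius,
                          noise_sigma = sp$noise_sigma,
                          background = sp$background, seed = pseed)
      generate_stack(spi, patient_id = pid, eye_id = paste0(pid, "_OD"),
                     label = labels[i])
    })
  })
}

#' Desk-scale phantom study: downscaled volumes ready for training
#'
#' Generates a labeled phantom dataset at reduced geometry (96 x 96 B-scans,
#' 64 slices per eye, 3 retinal bands, lesion radius 10 px, noise sigma 5) and
#' runs the preprocessing chain scaled proportionally (slices `[16, 48)`
#' sampled at stride 2, central 34 columns, resize to 48 x 48), yielding
#' 48 x 48 x 16 volumes. These are the conditions used by the package's
#' small-scale training experiments.
#'
#' @param n_patients number of patients
#' @param dn_fraction proportion of DN labels
#' @param seed integer seed
#' @return list of `oct_volume`s of shape 48 x 48 x 16
#' @export
study_phantom_volumes <- function(n_patients = 20L, dn_fraction = 0.5,
                                  seed = 1L) {
  sp <- phantom_spec(width = 96L, height = 96L, n_slices = 64L, n_layers = 3L,
                     lesion_radius = 10, noise_sigma = 5, seed = seed)
  ds <- generate_dataset(n_patients, dn_fraction, sp, seed = seed)
  cfg <- preprocess_config(slice_lo = 16L, slice_hi = 48L, sample_stride = 2L,
                           crop_width = 34L, out_xy = 48L, out_depth = 16L)
  preprocess_dataset(ds, cfg)
}

#' Write a B-scan stack as zero-padded grayscale PNG slices
#' @param stack a `bscan_stack`
#' @param dir output directory (created if missing)
#' @export
write_stack_png <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(stack$slices)) {
    png::writePNG(stack$slices[[i]] / 255,
                  file.path(dir, sprintf("slice_%04d.png", i - 1L)))
  }
  invisible(dir)
}

#' Write a phantom dataset: one directory per eye plus labels.tsv
#' @param stacks list of `bscan_stack`
#' @param dir output directory
#' @export
write_dataset <- function(stacks, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (st in stacks) write_stack_png(st, file.path(dir, st$eye_id))
  lab <- data.frame(patient_id = vapply(stacks, `[[`, "", "patient_id"),
                    eye_id = vapply(stacks, `[[`, "", "eye_id"),
                    label = vapply(stacks, `[[`, 0L, "label"))
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a directory of grayscale PNG slices back into a `bscan_stack`
#' @param dir slice directory
#' @param patient_id,eye_id,label metadata (label 0/1 or NA)
#' @export
read_stack_dir <- function(dir, patient_id = basename(dir),
                           eye_id = basename(dir), label = NA_integer_) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG slices found in ", dir)
  slices <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    mi <- round(m * 255)
    storage.mode(mi) <- "integer"
    mi
  })
  structure(list(slices = slices, patient_id = patient_id, eye_id = eye_id,
                 label = as.integer(label)),
            class = "bscan_stack")
}
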