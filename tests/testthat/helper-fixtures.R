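# Shared fixtures and independent oracles, all built in code at test time.

options(octlan.verbose = FALSE)

# small phantom geometry used across tests (96 x 96 slices, 64 per eye)
small_spec <- function(seed = 1L, ...) {
  phantom_spec(width = 96L, height = 96L, n_slices = 64L, n_layers = 3L,
               lesion_radius = 10, noise_sigma = 5, seed = seed, ...)
}

# matching preprocessing configuration yielding 48 x 48 x 16 volumes
small_cfg <- function(...) {
  preprocess_config(slice_lo = 16L, slice_hi = 48L, sample_stride = 2L,
                    crop_width = 34L, out_xy = 48L, out_depth = 16L, ...)
}

# a tiny 2-stage backbone on small inputs
micro_backbone <- function(channels = 4L) {
  backbone_config(18L, base_channels = channels, blocks_per_stage = c(1L, 1L),
                  stem_kernel = 3L, stem_pool = FALSE,
                  stage_taps = c("stage1", "stage2"))
}

# central-difference gradient of scalar-valued fun at x (vector/array/matrix)
num_grad <- function(fun, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fun(xp) - fun(xm)) / (2 * eps)
  }
  g
}

# brute-force binary dilation of mask by structuring element se (odd square
# matrix), by definition: output pixel is 1 iff se overlaps any input 1.
brute_dilate <- function(mask, se) {
  r <- (nrow(se) - 1L) %/% 2L
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  ones <- which(mask == 1L, arr.ind = TRUE)
  for (k in seq_len(nrow(ones))) {
    for (dy in -r:r) for (dx in -r:r) {
      if (se[dy + r + 1L, dx + r + 1L] == 0) next
      y <- ones[k, 1] + dy; x <- ones[k, 2] + dx
      if (y >= 1 && y <= H && x >= 1 && x <= W) out[y, x] <- 1L
    }
  }
  out
}

# brute-force mask-guided attention oracle: explicit loops over positions
brute_lam <- function(X, xb, par) {
  N <- nrow(X); C <- ncol(X)
  XL <- X * xb
  Q <- XL %*% par$Wq + matrix(par$bq, N, C, byrow = TRUE)
  V <- X %*% par$Wv + matrix(par$bv, N, C, byrow = TRUE)
  A <- matrix(0, N, C)
  for (i in seq_len(N)) {
    s <- numeric(N)
    for (j in seq_len(N)) s[j] <- sum(Q[i, ] * Q[j, ])
    w <- exp(s - max(s)); w <- w / sum(w)
    for (j in seq_len(N)) A[i, ] <- A[i, ] + w[j] * V[j, ]
    A[i, ] <- A[i, ] + V[i, ]
  }
  A
}
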