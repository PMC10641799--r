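# Small shared helpers.

octlan_log <- function(...) {
  if (isTRUE(getOption("octlan.verbose", TRUE))) message(...)
}

# Linear interpolation matrix mapping a length-n_from axis to n_to samples,
# with centers aligned (the usual image-resize convention).
interp_matrix <- function(n_from, n_to) {
  p <- (seq_len(n_to) - 0.5) * n_from / n_to - 0.5
  p <- pmin(pmax(p, 0), n_from - 1)
  i0 <- pmin(floor(p), n_from - 1)
  fr <- p - i0
  i1 <- pmin(i0 + 1, n_from - 1)
  M <- matrix(0, n_to, n_from)
  M[cbind(seq_len(n_to), i0 + 1)] <- M[cbind(seq_len(n_to), i0 + 1)] + (1 - fr)
  M[cbind(seq_len(n_to), i1 + 1)] <- M[cbind(seq_len(n_to), i1 + 1)] + fr
  M
}

#' Trilinear resize of a 3D array
#' @param a 3D numeric array
#' @param target_dim integer vector c(H, W, D)
#' @return resized array
#' @keywords internal
resize_trilinear <- function(a, target_dim) {
  d <- dim(a)
  stopifnot(length(d) == 3L, length(target_dim) == 3L)
  # axis 1
  a <- array(interp_matrix(d[1], target_dim[1]) %*% matrix(a, d[1]),
             c(target_dim[1], d[2], d[3]))
  # axis 2
  a <- aperm(a, c(2L, 1L, 3L))
  a <- array(interp_matrix(d[2], target_dim[2]) %*% matrix(a, d[2]),
             c(target_dim[2], target_dim[1], d[3]))
  a <- aperm(a, c(2L, 1L, 3L))
  # axis 3
  a <- aperm(a, c(3L, 1L, 2L))
  a <- array(interp_matrix(d[3], target_dim[3]) %*% matrix(a, d[3]),
             c(target_dim[3], target_dim[1], target_dim[2]))
  aperm(a, c(2L, 3L, 1L))
}

# Rotate + scale a 2D slice about its center (backward mapping). interp
# "bilinear" for intensities, "nearest" for binary masks; outside -> fill.
transform_slice <- function(img, angle_deg, scale, interp = "bilinear",
                            fill = 0) {
  d <- dim(img)
  th <- angle_deg * pi / 180
  cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
  yy <- rep(seq_len(d[1]), d[2]) - cy
  xx <- rep(seq_len(d[2]), each = d[1]) - cx
  # inverse transform: rotate by -theta, divide by scale
  sy <- ( cos(th) * yy + sin(th) * xx) / scale + cy
  sx <- (-sin(th) * yy + cos(th) * xx) / scale + cx
  if (interp == "nearest") {
    iy <- round(sy); ix <- round(sx)
    ok <- iy >= 1 & iy <= d[1] & ix >= 1 & ix <= d[2]
    out <- rep(fill, d[1] * d[2])
    out[ok] <- img[cbind(iy[ok], ix[ok])]
  } else {
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    gv <- function(iy, ix) {
      ok <- iy >= 1 & iy <= d[1] & ix >= 1 & ix <= d[2]
      v <- rep(fill, length(iy))
      v[ok] <- img[cbind(iy[ok], ix[ok])]
      v
    }
    out <- gv(y0, x0) * (1 - fy) * (1 - fx) + gv(y0 + 1, x0) * fy * (1 - fx) +
      gv(y0, x0 + 1) * (1 - fy) * fx + gv(y0 + 1, x0 + 1) * fy * fx
  }
  matrix(out, d[1], d[2])
}
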