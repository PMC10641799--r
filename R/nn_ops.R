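# Primitive differentiable operations for the 3D network engine.
#
# A feature map is a list(v = N x C matrix, d = c(H, W, D)) where N = H*W*D and
# rows are spatial positions in column-major (H fastest) order. All operations
# come in _fwd / _bwd pairs; _fwd returns list(out = ..., cache = ...) and _bwd
# consumes upstream gradients plus the cache. Everything is deterministic.

fmap <- function(v, d) {
  stopifnot(nrow(v) == prod(d))
  list(v = v, d = as.integer(d))
}

#' Convert a 3D (or 4D H x W x D x C) array to the internal feature-map form
#' @param a numeric array with 3 (single channel) or 4 dimensions
#' @return feature map list with matrix `v` (positions x channels) and `d`
#' @keywords internal
array_to_fmap <- function(a) {
  dm <- dim(a)
  if (length(dm) == 3L) dm <- c(dm, 1L)
  fmap(matrix(as.numeric(a), nrow = prod(dm[1:3]), ncol = dm[4]), dm[1:3])
}

fmap_to_array <- function(f) {
  array(f$v, c(f$d, ncol(f$v)))
}

# ---- im2col index machinery --------------------------------------------------

# Linear indices (1-based, into the zero-padded single-channel array) of each
# kernel element for each output position. Cached per geometry because index
# construction dominates when repeated every step.
.conv_idx_cache <- new.env(parent = emptyenv())

conv_index <- function(in_dim, k, stride, pad) {
  key <- paste(c(in_dim, k, stride, pad), collapse = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  H <- in_dim[1]; W <- in_dim[2]; D <- in_dim[3]
  Hp <- H + 2L * pad; Wp <- W + 2L * pad; Dp <- D + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  Do <- (Dp - k) %/% stride + 1L
  stopifnot(Ho >= 1L, Wo >= 1L, Do >= 1L)
  oh <- rep.int(seq_len(Ho), Wo * Do)
  ow <- rep.int(rep(seq_len(Wo), each = Ho), Do)
  od <- rep(seq_len(Do), each = Ho * Wo)
  base <- (oh - 1L) * stride + ((ow - 1L) * stride) * Hp +
    ((od - 1L) * stride) * (Hp * Wp) + 1L
  kh <- rep.int(seq_len(k) - 1L, k * k)
  kw <- rep.int(rep(seq_len(k) - 1L, each = k), k)
  kd <- rep(seq_len(k) - 1L, each = k * k)
  koff <- kh + kw * Hp + kd * (Hp * Wp)
  idx <- outer(base, koff, `+`)          # N x k^3, integer
  storage.mode(idx) <- "integer"
  res <- list(idx = idx, out_dim = c(Ho, Wo, Do), pad_dim = c(Hp, Wp, Dp))
  .conv_idx_cache[[key]] <- res
  res
}

# Pad an N x C position matrix into a padded-array vector per channel.
pad_fmap <- function(f, pad, value = 0) {
  H <- f$d[1]; W <- f$d[2]; D <- f$d[3]; C <- ncol(f$v)
  if (pad == 0L) return(f$v)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad; Dp <- D + 2L * pad
  out <- matrix(value, Hp * Wp * Dp, C)
  a <- array(out, c(Hp, Wp, Dp, C))
  a[pad + seq_len(H), pad + seq_len(W), pad + seq_len(D), ] <- f$v
  matrix(a, Hp * Wp * Dp, C)
}

# ---- 3D convolution ----------------------------------------------------------

#' Initialize 3D convolution weights (Kaiming fan-out)
#' @keywords internal
conv3d_init <- function(k, c_in, c_out) {
  fan_out <- k^3 * c_out
  matrix(stats::rnorm(k^3 * c_in * c_out, sd = sqrt(2 / fan_out)),
         nrow = k^3 * c_in, ncol = c_out)
}

conv3d_fwd <- function(f, W, stride = 1L, pad = 0L, bias = NULL) {
  k3 <- nrow(W) / ncol(f$v)
  k <- round(k3^(1 / 3))
  stopifnot(k^3 * ncol(f$v) == nrow(W))
  ci <- conv_index(f$d, k, as.integer(stride), as.integer(pad))
  xp <- pad_fmap(f, as.integer(pad))
  C_in <- ncol(f$v)
  # columns: for each input channel, gather its k^3 neighborhood values
  cols <- matrix(0, nrow(ci$idx), nrow(W))
  for (c in seq_len(C_in)) {
    cols[, ((c - 1L) * k3 + 1L):(c * k3)] <- xp[, c][ci$idx]
  }
  out <- cols %*% W
  if (!is.null(bias)) out <- sweep(out, 2L, bias, `+`)
  list(out = fmap(out, ci$out_dim),
       cache = list(cols = cols, W = W, ci = ci, in_dim = f$d,
                    C_in = C_in, k3 = k3, pad = as.integer(pad),
                    has_bias = !is.null(bias)))
}

conv3d_bwd <- function(dout, cache) {
  # dout: N_out x C_out matrix
  dW <- crossprod(cache$cols, dout)
  db <- if (cache$has_bias) colSums(dout) else NULL
  dcols <- dout %*% t(cache$W)                       # N_out x (k3*C_in)
  ci <- cache$ci; k3 <- cache$k3; pad <- cache$pad
  npad <- prod(ci$pad_dim)
  dx <- matrix(0, prod(cache$in_dim), cache$C_in)
  H <- cache$in_dim[1]; W_ <- cache$in_dim[2]; D <- cache$in_dim[3]
  iv <- as.vector(ci$idx)
  for (c in seq_len(cache$C_in)) {
    vals <- as.vector(dcols[, ((c - 1L) * k3 + 1L):(c * k3)])
    g <- rowsum(vals, iv)
    dxp <- numeric(npad)
    dxp[as.integer(rownames(g))] <- g
    if (pad > 0L) {
      a <- array(dxp, ci$pad_dim)
      dx[, c] <- a[pad + seq_len(H), pad + seq_len(W_), pad + seq_len(D)]
    } else {
      dx[, c] <- dxp
    }
  }
  list(dx = dx, dW = dW, db = db)
}

# ---- max pooling -------------------------------------------------------------

maxpool3d_fwd <- function(f, k = 3L, stride = 2L, pad = 1L) {
  ci <- conv_index(f$d, as.integer(k), as.integer(stride), as.integer(pad))
  xp <- pad_fmap(f, as.integer(pad), value = -Inf)
  C <- ncol(f$v)
  N <- nrow(ci$idx)
  out <- matrix(0, N, C)
  arg <- matrix(0L, N, C)
  for (c in seq_len(C)) {
    cols <- matrix(xp[, c][ci$idx], N)
    a <- max.col(cols, ties.method = "first")
    arg[, c] <- ci$idx[cbind(seq_len(N), a)]
    out[, c] <- cols[cbind(seq_len(N), a)]
  }
  list(out = fmap(out, ci$out_dim),
       cache = list(arg = arg, ci = ci, in_dim = f$d, pad = as.integer(pad), C = C))
}

maxpool3d_bwd <- function(dout, cache) {
  ci <- cache$ci; pad <- cache$pad
  H <- cache$in_dim[1]; W_ <- cache$in_dim[2]; D <- cache$in_dim[3]
  dx <- matrix(0, prod(cache$in_dim), cache$C)
  npad <- prod(ci$pad_dim)
  for (c in seq_len(cache$C)) {
    g <- rowsum(dout[, c], cache$arg[, c])
    dxp <- numeric(npad)
    dxp[as.integer(rownames(g))] <- g
    if (pad > 0L) {
      a <- array(dxp, ci$pad_dim)
      dx[, c] <- a[pad + seq_len(H), pad + seq_len(W_), pad + seq_len(D)]
    } else {
      dx[, c] <- dxp
    }
  }
  dx
}

# ---- instance normalization --------------------------------------------------

instnorm_fwd <- function(f, gamma, beta, eps = 1e-5) {
  n <- nrow(f$v)
  m <- colMeans(f$v)
  xc <- sweep(f$v, 2L, m)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, istd, `*`)
  out <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(out = fmap(out, f$d),
       cache = list(xhat = xhat, istd = istd, gamma = gamma, n = n, d = f$d))
}

instnorm_bwd <- function(dout, cache) {
  n <- cache$n
  dg <- colSums(dout * cache$xhat)
  db <- colSums(dout)
  dxhat <- sweep(dout, 2L, cache$gamma, `*`)
  # dx = istd/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- sweep(n * dxhat, 2L, s1) - sweep(cache$xhat, 2L, s2, `*`)
  dx <- sweep(dx, 2L, cache$istd / n, `*`)
  list(dx = dx, dgamma = dg, dbeta = db)
}

# ---- elementwise / head ops --------------------------------------------------

relu_fwd <- function(v) list(out = pmax(v, 0), cache = v > 0)
relu_bwd <- function(dout, cache) dout * cache

gap_fwd <- function(f) {
  list(out = colMeans(f$v), cache = list(n = nrow(f$v), d = f$d))
}
gap_bwd <- function(dout, cache) {
  matrix(rep(dout / cache$n, each = cache$n), cache$n, length(dout))
}

linear_fwd <- function(x, W, b) {
  list(out = as.vector(x %*% W + b), cache = list(x = x, W = W))
}
linear_bwd <- function(dout, cache) {
  list(dx = as.vector(dout %*% t(cache$W)),
       dW = outer(as.vector(cache$x), dout), db = dout)
}

#' Numerically stable softmax of a score vector
#' @param s numeric vector of scores
#' @keywords internal
softmax_vec <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

# Cross-entropy loss on logits for a single sample; label is 1-based class.
xent_fwd <- function(scores, label) {
  p <- softmax_vec(scores)
  list(loss = -log(max(p[label], 1e-12)), p = p)
}
xent_bwd <- function(p, label) {
  d <- p
  d[label] <- d[label] - 1
  d
}

# Row-wise softmax of a matrix (each row sums to 1).
softmax_rows <- function(S) {
  mx <- apply(S, 1L, max)
  E <- exp(S - mx)
  E / rowSums(E)
}

# ---- Adam optimizer ----------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Step learning-rate schedule: lr * gamma^floor(epoch / step_size), epoch 0-based.
steplr <- function(lr0, epoch, step_size, gamma) {
  lr0 * gamma^(epoch %/% step_size)
}
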