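# Lesion-aware attention module (LAM).
#
# A self-attention block whose query/key features are computed from the
# mask-gated feature map: X_L = X (.) X_B, X_LC = conv1(X_L), X_C = conv2(X),
# A_L = softmax(X_LC X_LC^T) X_C + X_C  (rowwise softmax over the N spatial
# positions). The residual "+ X_C" keeps the value-projected original features
# so a coarse mask cannot erase information. The 1x1x1 convolutions preserve
# the channel count, so A_L can replace X inside the backbone.
#
# An alternative "literal" composition softmax(X_LC X_LC^T X_C) + X_C is
# available behind `variant = "literal"`; the standard attention reading is
# the default (see the methods vignette for the rationale).

#' Configuration for attention insertion into the backbone
#'
#' @param insertion `"per_stage"` (one module after the last block of every
#'   stage) or `"per_block"` (one after every residual block)
#' @param mask_resample `"nearest"` (keeps the mask binary) or `"trilinear"`
#' @param variant `"standard"` attention composition or `"literal"`
#' @param sites optional character vector restricting insertion to specific
#'   sites (`"s2"` for a stage, `"s2.b1"` for a block), overriding `insertion`
#' @export
lam_config <- function(insertion = c("per_stage", "per_block"),
                       mask_resample = c("nearest", "trilinear"),
                       variant = c("standard", "literal"),
                       sites = NULL) {
  structure(list(insertion = match.arg(insertion),
                 mask_resample = match.arg(mask_resample),
                 variant = match.arg(variant),
                 sites = sites),
            class = "lam_config")
}

# Name of the insertion site at (stage s, block b) for this model, or NULL if
# the model has no attention there.
lam_site_name <- function(model, s, b) {
  if (is.null(model$lam)) return(NULL)
  if (model$lam$insertion == "per_block") return(sprintf("s%d.b%d", s, b))
  if (b == length(model$plan$stages[[s]])) return(sprintf("s%d", s))
  NULL
}

lam_init_params <- function(C) {
  list(Wq = matrix(stats::rnorm(C * C, sd = sqrt(2 / C)), C, C),
       bq = rep(0, C),
       Wv = matrix(stats::rnorm(C * C, sd = sqrt(2 / C)), C, C),
       bv = rep(0, C))
}

#' Resample a binary 3D mask to a target spatial grid (nearest neighbor)
#' @param mask 3D array in {0,1}
#' @param target_dim integer vector c(H, W, D)
#' @keywords internal
resample_mask_nearest <- function(mask, target_dim) {
  sd_ <- dim(mask)
  pick <- function(n_to, n_from) pmin(pmax(ceiling((seq_len(n_to) - 0.5) * n_from / n_to), 1L), n_from)
  mask[pick(target_dim[1], sd_[1]), pick(target_dim[2], sd_[2]),
       pick(target_dim[3], sd_[3]), drop = FALSE]
}

resample_mask_trilinear <- function(mask, target_dim) {
  resize_trilinear(mask, target_dim)
}

# internal forward: f is a feature map, mask a full-resolution 3D array (or a
# vector already matching f's grid).
lam_fwd <- function(f, mask, par, variant = "standard", resample = "nearest") {
  if (is.array(mask) && !all(dim(mask) == f$d)) {
    mask <- if (resample == "trilinear") resample_mask_trilinear(mask, f$d)
            else resample_mask_nearest(mask, f$d)
  }
  xb <- as.numeric(mask)
  if (length(xb) != nrow(f$v)) stop("mask does not match the feature grid")
  X <- f$v
  XL <- X * xb
  Q <- sweep(XL %*% par$Wq, 2L, par$bq, `+`)
  V <- sweep(X %*% par$Wv, 2L, par$bv, `+`)
  S <- tcrossprod(Q)                     # N x N
  if (variant == "standard") {
    P <- softmax_rows(S)
    A <- P %*% V + V
  } else {
    M <- S %*% V                         # N x C
    P <- softmax_rows(M)
    A <- P + V
  }
  list(out = fmap(A, f$d),
       cache = list(X = X, XL = XL, Q = Q, V = V, S = S, P = P, xb = xb,
                    par = par, variant = variant, d = f$d))
}

lam_bwd <- function(dA, cache) {
  par <- cache$par
  if (cache$variant == "standard") {
    dV <- crossprod(cache$P, dA) + dA
    dP <- tcrossprod(dA, cache$V)        # dA %*% t(V)
    dS <- cache$P * (dP - rowSums(dP * cache$P))
  } else {
    dP <- dA
    dM <- cache$P * (dP - rowSums(dP * cache$P))
    dS <- tcrossprod(dM, cache$V)        # dM %*% t(V)
    dV <- crossprod(cache$S, dM) + dA
  }
  dQ <- (dS + t(dS)) %*% cache$Q
  dXL <- tcrossprod(dQ, par$Wq)          # dQ %*% t(Wq)
  grads <- list(Wq = crossprod(cache$XL, dQ), bq = colSums(dQ),
                Wv = crossprod(cache$X, dV), bv = colSums(dV))
  dx <- tcrossprod(dV, par$Wv) + dXL * cache$xb
  list(dx = dx, grads = grads)
}

#' Apply the lesion-aware attention module to a feature map
#'
#' Standalone forward pass of the module: gates the features with the binary
#' lesion mask, computes query/key projections from the gated features and a
#' value projection from the original features, applies rowwise-softmax
#' self-attention over all spatial positions, and adds the value projection
#' back.
#'
#' @param X 4D array (H x W x D x C) or an internal feature map
#' @param mask binary array at X's spatial grid (or full volume resolution,
#'   in which case it is resampled by nearest neighbor)
#' @param params list with `Wq`, `bq`, `Wv`, `bv` (`C x C` matrices and length
#'   `C` vectors), e.g. from the model or random for testing
#' @param variant `"standard"` or `"literal"` composition (see above)
#' @return 4D array `A_L` of the same shape as `X`
#' @export
lam_forward <- function(X, mask, params, variant = "standard") {
  f <- if (is.list(X) && !is.null(X$v)) X else array_to_fmap(X)
  if (ncol(f$v) != nrow(params$Wq)) {
    stop("params channel count (", nrow(params$Wq),
         ") does not match X (", ncol(f$v), ")")
  }
  r <- lam_fwd(f, mask, params, variant = variant)
  fmap_to_array(r$out)
}

#' Build the lesion-aware attention network
#'
#' The backbone of `backbone_cfg` with an attention module at every insertion
#' site of `lam_cfg`. The forward pass takes `(volume, mask)`; the mask is
#' resampled to each site's grid.
#'
#' @param backbone_cfg a [backbone_config()]
#' @param lam_cfg a [lam_config()]
#' @param backbone optional already-built (e.g. stage-1 trained) backbone whose
#'   weights are reused; its config must equal `backbone_cfg`
#' @return model handle with attention parameters under `lam`
#' @export
build_lam_network <- function(backbone_cfg, lam_cfg = lam_config(),
                              backbone = NULL) {
  model <- if (is.null(backbone)) build_backbone(backbone_cfg) else backbone
  sites <- list()
  for (s in seq_along(model$plan$stages)) {
    nb <- length(model$plan$stages[[s]])
    for (b in seq_len(nb)) {
      nm <- if (lam_cfg$insertion == "per_block") sprintf("s%d.b%d", s, b)
            else if (b == nb) sprintf("s%d", s) else NULL
      if (is.null(nm)) next
      if (!is.null(lam_cfg$sites) && !nm %in% lam_cfg$sites) next
      sites[[nm]] <- lam_init_params(model$plan$stages[[s]][[b]]$c_out)
    }
  }
  model$lam <- list(params = sites, insertion = lam_cfg$insertion,
                    mask_resample = lam_cfg$mask_resample,
                    variant = lam_cfg$variant)
  model$lam_cfg <- lam_cfg
  # attention parameters join the flat parameter list for the optimizer
  for (nm in names(sites)) {
    for (pn in names(sites[[nm]])) {
      model$params[[paste0("lam.", nm, ".", pn)]] <- sites[[nm]][[pn]]
    }
  }
  model
}

# The flat model$params list is authoritative for attention weights during
# training; model$lam$params records the sites and their initial values.
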