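# 3D residual network backbone with named feature taps.
#
# The model handle is a plain list: cfg, plan (static layer geometry), params
# (flat named list of numeric arrays), and optionally $lam (attention sites,
# see lam.R). Forward/backward walk the plan explicitly; caches carry exactly
# what the hand-written backward passes need.

.depth_table <- list(
  `18`  = list(block = "basic",      blocks = c(2L, 2L, 2L, 2L)),
  `34`  = list(block = "basic",      blocks = c(3L, 4L, 6L, 3L)),
  `50`  = list(block = "bottleneck", blocks = c(3L, 4L, 6L, 3L)),
  `101` = list(block = "bottleneck", blocks = c(3L, 4L, 23L, 3L))
)

#' Configuration for the 3D residual backbone
#'
#' Canonical depths follow the ResNet family (basic blocks for 18/34,
#' bottleneck blocks for 50/101), generalized to 3D: every convolution and
#' pooling operation acts on all three spatial axes, and stage strides
#' downsample depth together with height and width. `blocks_per_stage`,
#' `base_channels` and the stem options allow scaled-down variants for small
#' volumes.
#'
#' @param depth one of 18, 34, 50, 101
#' @param n_classes number of output classes (>= 2)
#' @param base_channels channels of the first stage (64 for canonical ResNet)
#' @param blocks_per_stage optional integer vector overriding the canonical
#'   per-stage block counts; its length sets the number of stages
#' @param stem_kernel stem convolution kernel size (canonical: 7)
#' @param stem_stride stem convolution stride (canonical: 2)
#' @param stem_pool logical; apply 3x3x3 stride-2 max pooling after the stem
#' @param stage_taps character vector of stage names exposed as feature taps
#' @return a `backbone_config` list
#' @export
backbone_config <- function(depth = 18L, n_classes = 2L, base_channels = 64L,
                            blocks_per_stage = NULL, stem_kernel = 7L,
                            stem_stride = 2L, stem_pool = TRUE,
                            stage_taps = NULL) {
  depth <- as.integer(depth)
  if (!as.character(depth) %in% names(.depth_table)) {
    stop("unsupported depth ", depth, "; must be one of 18, 34, 50, 101")
  }
  if (n_classes < 2L) stop("n_classes must be >= 2")
  dt <- .depth_table[[as.character(depth)]]
  blocks <- if (is.null(blocks_per_stage)) dt$blocks else as.integer(blocks_per_stage)
  n_stages <- length(blocks)
  if (is.null(stage_taps)) stage_taps <- paste0("stage", n_stages)
  structure(list(depth = depth, n_classes = as.integer(n_classes),
                 base_channels = as.integer(base_channels),
                 block = dt$block, blocks = blocks, n_stages = n_stages,
                 stem_kernel = as.integer(stem_kernel),
                 stem_stride = as.integer(stem_stride),
                 stem_pool = isTRUE(stem_pool),
                 stage_taps = stage_taps),
            class = "backbone_config")
}

#' A small backbone preset for downscaled volumes
#'
#' Two stages of one basic block each, narrow channels, 3x3x3 stem. Intended
#' for experiments on volumes around 48 x 48 x 16.
#' @param base_channels stage-1 width
#' @param n_classes number of classes
#' @export
tiny_backbone_config <- function(base_channels = 8L, n_classes = 2L) {
  backbone_config(depth = 18L, n_classes = n_classes,
                  base_channels = base_channels,
                  blocks_per_stage = c(1L, 1L), stem_kernel = 3L,
                  stem_stride = 2L, stem_pool = TRUE,
                  stage_taps = c("stage1", "stage2"))
}

# Static plan: channel counts and strides for every block.
build_plan <- function(cfg) {
  expansion <- if (cfg$block == "bottleneck") 4L else 1L
  stages <- vector("list", cfg$n_stages)
  c_in <- cfg$base_channels
  for (s in seq_len(cfg$n_stages)) {
    inner <- cfg$base_channels * 2L^(s - 1L)
    c_out <- inner * expansion
    blocks <- vector("list", cfg$blocks[s])
    for (b in seq_len(cfg$blocks[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      blocks[[b]] <- list(c_in = c_in, inner = inner, c_out = c_out,
                          stride = stride,
                          downsample = (stride != 1L || c_in != c_out))
      c_in <- c_out
    }
    stages[[s]] <- blocks
  }
  list(stages = stages, out_channels = c_in, expansion = expansion)
}

#' Build a 3D residual backbone
#'
#' @param cfg a [backbone_config()]
#' @param input_channels channels of the input volume (1 for grayscale OCT)
#' @return a model handle (list with `cfg`, `plan`, `params`)
#' @export
build_backbone <- function(cfg, input_channels = 1L) {
  stopifnot(inherits(cfg, "backbone_config"))
  plan <- build_plan(cfg)
  p <- list()
  p[["stem.W"]] <- conv3d_init(cfg$stem_kernel, input_channels, cfg$base_channels)
  p[["stem.g"]] <- rep(1, cfg$base_channels)
  p[["stem.be"]] <- rep(0, cfg$base_channels)
  for (s in seq_along(plan$stages)) {
    for (b in seq_along(plan$stages[[s]])) {
      bl <- plan$stages[[s]][[b]]
      key <- function(x) sprintf("s%d.b%d.%s", s, b, x)
      if (cfg$block == "basic") {
        p[[key("W1")]] <- conv3d_init(3L, bl$c_in, bl$c_out)
        p[[key("W2")]] <- conv3d_init(3L, bl$c_out, bl$c_out)
        p[[key("g1")]] <- rep(1, bl$c_out); p[[key("be1")]] <- rep(0, bl$c_out)
        p[[key("g2")]] <- rep(1, bl$c_out); p[[key("be2")]] <- rep(0, bl$c_out)
      } else {
        p[[key("W1")]] <- conv3d_init(1L, bl$c_in, bl$inner)
        p[[key("W2")]] <- conv3d_init(3L, bl$inner, bl$inner)
        p[[key("W3")]] <- conv3d_init(1L, bl$inner, bl$c_out)
        p[[key("g1")]] <- rep(1, bl$inner); p[[key("be1")]] <- rep(0, bl$inner)
        p[[key("g2")]] <- rep(1, bl$inner); p[[key("be2")]] <- rep(0, bl$inner)
        p[[key("g3")]] <- rep(1, bl$c_out); p[[key("be3")]] <- rep(0, bl$c_out)
      }
      if (bl$downsample) {
        p[[key("down.W")]] <- conv3d_init(1L, bl$c_in, bl$c_out)
        p[[key("down.g")]] <- rep(1, bl$c_out)
        p[[key("down.be")]] <- rep(0, bl$c_out)
      }
    }
  }
  p[["head.W"]] <- matrix(stats::rnorm(plan$out_channels * cfg$n_classes,
                                       sd = sqrt(1 / plan$out_channels)),
                          plan$out_channels, cfg$n_classes)
  p[["head.b"]] <- rep(0, cfg$n_classes)
  structure(list(cfg = cfg, plan = plan, params = p, lam = NULL),
            class = "octlan_model")
}

# ---- block forward/backward --------------------------------------------------

block_fwd <- function(p, key, type, x, stride) {
  k <- function(s) p[[paste0(key, ".", s)]]
  cache <- list(type = type)
  if (type == "basic") {
    c1 <- conv3d_fwd(x, k("W1"), stride, 1L); cache$c1 <- c1$cache
    n1 <- instnorm_fwd(c1$out, k("g1"), k("be1")); cache$n1 <- n1$cache
    r1 <- relu_fwd(n1$out$v); cache$r1 <- r1$cache
    f1 <- fmap(r1$out, n1$out$d)
    c2 <- conv3d_fwd(f1, k("W2"), 1L, 1L); cache$c2 <- c2$cache
    n2 <- instnorm_fwd(c2$out, k("g2"), k("be2")); cache$n2 <- n2$cache
    main <- n2$out
  } else {
    c1 <- conv3d_fwd(x, k("W1"), 1L, 0L); cache$c1 <- c1$cache
    n1 <- instnorm_fwd(c1$out, k("g1"), k("be1")); cache$n1 <- n1$cache
    r1 <- relu_fwd(n1$out$v); cache$r1 <- r1$cache
    c2 <- conv3d_fwd(fmap(r1$out, n1$out$d), k("W2"), stride, 1L); cache$c2 <- c2$cache
    n2 <- instnorm_fwd(c2$out, k("g2"), k("be2")); cache$n2 <- n2$cache
    r2 <- relu_fwd(n2$out$v); cache$r2 <- r2$cache
    c3 <- conv3d_fwd(fmap(r2$out, n2$out$d), k("W3"), 1L, 0L); cache$c3 <- c3$cache
    n3 <- instnorm_fwd(c3$out, k("g3"), k("be3")); cache$n3 <- n3$cache
    main <- n3$out
  }
  if (!is.null(k("down.W"))) {
    cd <- conv3d_fwd(x, k("down.W"), stride, 0L); cache$cd <- cd$cache
    nd <- instnorm_fwd(cd$out, k("down.g"), k("down.be")); cache$nd <- nd$cache
    sc <- nd$out$v
    cache$identity_sc <- FALSE
  } else {
    sc <- x$v
    cache$identity_sc <- TRUE
  }
  pre <- main$v + sc
  r <- relu_fwd(pre); cache$r_out <- r$cache
  list(out = fmap(r$out, main$d), cache = cache)
}

block_bwd <- function(p, key, cache, dout) {
  k <- function(s) p[[paste0(key, ".", s)]]
  g <- list()
  gkey <- function(s) paste0(key, ".", s)
  dpre <- relu_bwd(dout, cache$r_out)
  if (cache$type == "basic") {
    bn2 <- instnorm_bwd(dpre, cache$n2)
    g[[gkey("g2")]] <- bn2$dgamma; g[[gkey("be2")]] <- bn2$dbeta
    bc2 <- conv3d_bwd(bn2$dx, cache$c2)
    g[[gkey("W2")]] <- bc2$dW
    dr1 <- relu_bwd(bc2$dx, cache$r1)
    bn1 <- instnorm_bwd(dr1, cache$n1)
    g[[gkey("g1")]] <- bn1$dgamma; g[[gkey("be1")]] <- bn1$dbeta
    bc1 <- conv3d_bwd(bn1$dx, cache$c1)
    g[[gkey("W1")]] <- bc1$dW
    dx_main <- bc1$dx
  } else {
    bn3 <- instnorm_bwd(dpre, cache$n3)
    g[[gkey("g3")]] <- bn3$dgamma; g[[gkey("be3")]] <- bn3$dbeta
    bc3 <- conv3d_bwd(bn3$dx, cache$c3)
    g[[gkey("W3")]] <- bc3$dW
    dr2 <- relu_bwd(bc3$dx, cache$r2)
    bn2 <- instnorm_bwd(dr2, cache$n2)
    g[[gkey("g2")]] <- bn2$dgamma; g[[gkey("be2")]] <- bn2$dbeta
    bc2 <- conv3d_bwd(bn2$dx, cache$c2)
    g[[gkey("W2")]] <- bc2$dW
    dr1 <- relu_bwd(bc2$dx, cache$r1)
    bn1 <- instnorm_bwd(dr1, cache$n1)
    g[[gkey("g1")]] <- bn1$dgamma; g[[gkey("be1")]] <- bn1$dbeta
    bc1 <- conv3d_bwd(bn1$dx, cache$c1)
    g[[gkey("W1")]] <- bc1$dW
    dx_main <- bc1$dx
  }
  if (cache$identity_sc) {
    dx <- dx_main + dpre
  } else {
    bnd <- instnorm_bwd(dpre, cache$nd)
    g[[gkey("down.g")]] <- bnd$dgamma; g[[gkey("down.be")]] <- bnd$dbeta
    bcd <- conv3d_bwd(bnd$dx, cache$cd)
    g[[gkey("down.W")]] <- bcd$dW
    dx <- dx_main + bcd$dx
  }
  list(dx = dx, grads = g)
}

# ---- full network forward/backward ------------------------------------------

as_input_fmap <- function(volume) {
  if (inherits(volume, "oct_volume")) volume <- volume$data
  if (is.list(volume) && !is.null(volume$v)) return(volume)
  array_to_fmap(volume)
}

#' Forward pass of a (possibly attention-augmented) backbone
#'
#' @param model handle from [build_backbone()] or [build_lam_network()]
#' @param volume an `oct_volume`, a 3D array, or an internal feature map
#' @param mask optional binary lesion mask array at volume resolution; required
#'   when the model carries attention sites
#' @param keep_cache retain intermediate activations for a backward pass
#' @return list with `scores` (length `n_classes`), `taps` (named feature
#'   maps), and `cache` when requested
#' @export
net_forward <- function(model, volume, mask = NULL, keep_cache = FALSE) {
  x <- as_input_fmap(volume)
  p <- model$params
  cfg <- model$cfg
  lam_sites <- if (!is.null(model$lam)) names(model$lam$params) else character(0)
  if (length(lam_sites) > 0 && is.null(mask)) {
    stop("this model has attention sites; a lesion mask is required")
  }
  cache <- list(in_dim = x$d)
  cs <- conv3d_fwd(x, p[["stem.W"]], cfg$stem_stride,
                   (cfg$stem_kernel - 1L) %/% 2L)
  cache$stem_conv <- cs$cache
  ns <- instnorm_fwd(cs$out, p[["stem.g"]], p[["stem.be"]])
  cache$stem_norm <- ns$cache
  rs <- relu_fwd(ns$out$v); cache$stem_relu <- rs$cache
  h <- fmap(rs$out, ns$out$d)
  if (cfg$stem_pool) {
    mp <- maxpool3d_fwd(h); cache$stem_pool <- mp$cache
    h <- mp$out
  }
  taps <- list()
  cache$stages <- vector("list", cfg$n_stages)
  for (s in seq_len(cfg$n_stages)) {
    nb <- length(model$plan$stages[[s]])
    cache$stages[[s]] <- vector("list", nb)
    for (b in seq_len(nb)) {
      key <- sprintf("s%d.b%d", s, b)
      bl <- model$plan$stages[[s]][[b]]
      bf <- block_fwd(p, key, cfg$block, h, bl$stride)
      bc <- list(block = bf$cache)
      h <- bf$out
      site <- lam_site_name(model, s, b)
      if (!is.null(site) && site %in% lam_sites) {
        lpar <- list(Wq = p[[paste0("lam.", site, ".Wq")]],
                     bq = p[[paste0("lam.", site, ".bq")]],
                     Wv = p[[paste0("lam.", site, ".Wv")]],
                     bv = p[[paste0("lam.", site, ".bv")]])
        lf <- lam_fwd(h, mask, lpar,
                      variant = model$lam$variant,
                      resample = model$lam$mask_resample)
        bc$lam <- lf$cache
        bc$lam_site <- site
        h <- lf$out
      }
      cache$stages[[s]][[b]] <- bc
    }
    taps[[paste0("stage", s)]] <- h
  }
  gp <- gap_fwd(h); cache$gap <- gp$cache
  hd <- linear_fwd(matrix(gp$out, 1L), p[["head.W"]], p[["head.b"]])
  cache$head <- hd$cache
  out <- list(scores = hd$out, taps = taps)
  if (keep_cache) out$cache <- cache
  out
}

#' Backward pass: parameter gradients and gradients at stage taps
#'
#' @param model model handle
#' @param cache cache from `net_forward(..., keep_cache = TRUE)`
#' @param dscores gradient of the objective w.r.t. the class scores
#' @param tap_grads character vector of stage names whose activation gradients
#'   should be returned (used by Grad-CAM)
#' @return list with `grads` (named like `model$params`) and `tap_grads`
#' @export
net_backward <- function(model, cache, dscores, tap_grads = character(0)) {
  p <- model$params
  cfg <- model$cfg
  g <- list()
  bh <- linear_bwd(dscores, cache$head)
  g[["head.W"]] <- bh$dW; g[["head.b"]] <- bh$db
  dh <- gap_bwd(bh$dx, cache$gap)
  tg <- list()
  for (s in rev(seq_len(cfg$n_stages))) {
    if (paste0("stage", s) %in% tap_grads) tg[[paste0("stage", s)]] <- dh
    for (b in rev(seq_along(cache$stages[[s]]))) {
      bc <- cache$stages[[s]][[b]]
      if (!is.null(bc$lam)) {
        lb <- lam_bwd(dh, bc$lam)
        for (nm in names(lb$grads)) {
          g[[paste0("lam.", bc$lam_site, ".", nm)]] <- lb$grads[[nm]]
        }
        dh <- lb$dx
      }
      key <- sprintf("s%d.b%d", s, b)
      bb <- block_bwd(p, key, bc$block, dh)
      g <- c(g, bb$grads)
      dh <- bb$dx
    }
  }
  if (cfg$stem_pool) dh <- maxpool3d_bwd(dh, cache$stem_pool)
  dh <- relu_bwd(dh, cache$stem_relu)
  bn <- instnorm_bwd(dh, cache$stem_norm)
  g[["stem.g"]] <- bn$dgamma; g[["stem.be"]] <- bn$dbeta
  bc <- conv3d_bwd(bn$dx, cache$stem_conv)
  g[["stem.W"]] <- bc$dW
  list(grads = g, dx = bc$dx, tap_grads = tg)
}

#' Forward pass returning class scores and activations at named taps
#'
#' @param model model handle
#' @param volume input volume
#' @param taps character vector of tap names (default: the config's
#'   `stage_taps`); each must be one of `stage1..stageN`
#' @param mask optional lesion mask (attention models only)
#' @return list with `scores` and `features` (named list of 4D
#'   H x W x D x C arrays)
#' @export
forward_with_features <- function(model, volume, taps = NULL, mask = NULL) {
  if (is.null(taps)) taps <- model$cfg$stage_taps
  valid <- paste0("stage", seq_len(model$cfg$n_stages))
  bad <- setdiff(taps, valid)
  if (length(bad) > 0) {
    stop("unknown tap name(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(valid, collapse = ", "))
  }
  fw <- net_forward(model, volume, mask = mask)
  list(scores = fw$scores,
       features = lapply(fw$taps[taps], fmap_to_array))
}

#' Save a model checkpoint (weights + configuration)
#' @param model model handle
#' @param path file path (`.rds`)
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(cfg = model$cfg, params = model$params,
              lam_cfg = model$lam_cfg, lam = model$lam)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#' @param path file path
#' @return model handle
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  m <- structure(list(cfg = obj$cfg, plan = build_plan(obj$cfg),
                      params = obj$params, lam = obj$lam,
                      lam_cfg = obj$lam_cfg),
                 class = "octlan_model")
  m
}

# Deterministic checksum of a model's parameters (cache keys, provenance).
model_checksum <- function(model) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(model$params, con, version = 3L)
  close(con)
  unname(tools::md5sum(tf))
}
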