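# Two-stage training: stage 1 trains the plain backbone; stage 2 derives a
# binary lesion mask per volume from the stage-1 model's Grad-CAM and trains
# the attention-augmented network on (volume, mask) pairs. Optimization is
# Adam with cross-entropy loss and a step learning-rate schedule; augmentation
# is in-plane random rotation and scaling, the identical transform applied to
# a volume and (in stage 2) its mask.

#' Training configuration
#'
#' @param epochs number of epochs
#' @param batch_size minibatch size (gradients averaged over the batch)
#' @param lr initial Adam learning rate
#' @param step_size,gamma step schedule: the rate is multiplied by `gamma`
#'   every `step_size` epochs
#' @param rotate_deg augmentation: rotation drawn uniformly in +/- this many
#'   degrees (0 disables rotation)
#' @param scale_range augmentation: isotropic in-plane scale drawn uniformly
#'   in this interval
#' @param augment enable augmentation
#' @param seed integer seed for initialization, shuffling and augmentation
#' @export
train_config <- function(epochs = 150L, batch_size = 2L, lr = 1e-4,
                         step_size = 50L, gamma = 0.1, rotate_deg = 10,
                         scale_range = c(0.9, 1.1), augment = TRUE,
                         seed = 1L) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (lr < 0) stop("lr must be >= 0")
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, step_size = as.integer(step_size), gamma = gamma,
                 rotate_deg = rotate_deg, scale_range = scale_range,
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "train_config")
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(cfg, con, version = 3L)
  close(con)
  unname(tools::md5sum(tf))
}

#' Random in-plane rotation and scaling of a volume (and matching mask)
#'
#' Draws one angle and one scale from the configuration's ranges using the
#' current RNG stream and applies the identical transform to every depth slice
#' (bilinear for intensities, nearest for the mask, zero fill outside);
#' intensities are re-clipped to `[0, 1]`.
#'
#' @param volume 3D array or `oct_volume`
#' @param cfg a [train_config()]
#' @param mask optional binary 3D array transformed identically
#' @return list with `data` (and `mask` when given) plus the drawn `angle`
#'   and `scale`
#' @export
augment_volume <- function(volume, cfg = train_config(), mask = NULL) {
  a <- if (inherits(volume, "oct_volume")) volume$data else volume
  angle <- stats::runif(1, -cfg$rotate_deg, cfg$rotate_deg)
  scale <- stats::runif(1, cfg$scale_range[1], cfg$scale_range[2])
  out <- a
  if (angle != 0 || scale != 1) {
    for (d in seq_len(dim(a)[3])) {
      out[, , d] <- transform_slice(a[, , d], angle, scale)
    }
    out <- pmin(pmax(out, 0), 1)
    if (!is.null(mask)) {
      mout <- mask
      for (d in seq_len(dim(mask)[3])) {
        mout[, , d] <- transform_slice(mask[, , d], angle, scale,
                                       interp = "nearest")
      }
      mask <- mout
    }
  }
  list(data = out, mask = mask, angle = angle, scale = scale)
}

zero_grads_like <- function(params) lapply(params, function(p) p * 0)

accumulate_grads <- function(acc, g) {
  for (nm in names(g)) {
    if (is.null(g[[nm]])) next
    acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
  }
  acc
}

# Shared minibatch training loop over (volume, mask) samples. masks may be
# NULL (baseline) or a list parallel to volumes.
run_training <- function(model, volumes, labels, cfg, masks = NULL) {
  n <- length(volumes)
  state <- adam_init(model$params)
  loss_curve <- numeric(cfg$epochs)
  lr_curve <- numeric(cfg$epochs)
  arrays <- lapply(volumes, function(v) if (inherits(v, "oct_volume")) v$data else v)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- steplr(cfg$lr, epoch - 1L, cfg$step_size, cfg$gamma)
    lr_curve[epoch] <- lr
    ord <- sample.int(n)
    ep_loss <- 0
    starts <- seq.int(1L, n, by = cfg$batch_size)
    for (st in starts) {
      ids <- ord[st:min(st + cfg$batch_size - 1L, n)]
      acc <- list()
      bl <- 0
      for (i in ids) {
        x <- arrays[[i]]
        msk <- if (!is.null(masks)) masks[[i]] else NULL
        if (cfg$augment) {
          ag <- augment_volume(x, cfg, mask = msk)
          x <- ag$data
          if (!is.null(msk)) msk <- ag$mask
        }
        fw <- net_forward(model, x, mask = msk, keep_cache = TRUE)
        xe <- xent_fwd(fw$scores, labels[i] + 1L)
        if (!is.finite(xe$loss)) stop("non-finite loss at epoch ", epoch)
        bl <- bl + xe$loss
        dscores <- xent_bwd(xe$p, labels[i] + 1L) / length(ids)
        bw <- net_backward(model, fw$cache, dscores)
        acc <- accumulate_grads(acc, bw$grads)
      }
      upd <- adam_step(model$params, acc, state, lr)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + bl
    }
    loss_curve[epoch] <- ep_loss / n
    octlan_log(sprintf("epoch %3d  lr %.2e  loss %.4f", epoch, lr,
                       loss_curve[epoch]))
  }
  list(model = model, loss_curve = loss_curve, lr_curve = lr_curve)
}

model_accuracy <- function(model, volumes, labels, masks = NULL) {
  pred <- vapply(seq_along(volumes), function(i) {
    msk <- if (!is.null(masks)) masks[[i]] else NULL
    which.max(net_forward(model, volumes[[i]], mask = msk)$scores) - 1L
  }, 0L)
  mean(pred == labels)
}

#' Stage 1: train the plain backbone
#'
#' @param volumes list of `oct_volume`s (or 3D arrays)
#' @param labels integer labels 0 (DR) / 1 (DN); taken from the volumes when
#'   NULL
#' @param backbone_cfg a [backbone_config()]
#' @param train_cfg a [train_config()]
#' @param checkpoint optional path; the trained model is saved there
#' @return a `stage_result`: `model`, `checkpoint`, `loss_curve`, `lr_curve`,
#'   `final_train_acc`, `seed`, `config_hash`
#' @export
train_stage1 <- function(volumes, labels = NULL, backbone_cfg, train_cfg,
                         checkpoint = NULL) {
  if (is.null(labels)) labels <- vapply(volumes, `[[`, 0L, "label")
  if (length(unique(labels)) < 2L) {
    stop("training labels contain a single class; need at least two")
  }
  set.seed(train_cfg$seed)
  model <- build_backbone(backbone_cfg)
  tr <- run_training(model, volumes, labels, train_cfg)
  acc <- model_accuracy(tr$model, volumes, labels)
  if (!is.null(checkpoint)) save_checkpoint(tr$model, checkpoint)
  structure(list(model = tr$model, checkpoint = checkpoint,
                 loss_curve = tr$loss_curve, lr_curve = tr$lr_curve,
                 final_train_acc = acc, seed = train_cfg$seed,
                 config_hash = config_hash(list(backbone_cfg, train_cfg))),
            class = "stage_result")
}

resolve_stage1 <- function(stage1) {
  if (inherits(stage1, "stage_result")) return(stage1$model)
  if (is.character(stage1)) return(load_checkpoint(stage1))
  stage1
}

#' Stage 2: generate masks from the stage-1 model and train the attention
#' network
#'
#' Lesion masks are produced once from the stage-1 model's Grad-CAM
#' ([batch_generate_masks()]) and stay fixed for the whole stage; the
#' attention network warm-starts from the stage-1 backbone weights (fresh
#' attention parameters) unless `warm_start = FALSE`.
#'
#' @param volumes list of `oct_volume`s
#' @param labels integer labels; taken from the volumes when NULL
#' @param stage1 a `stage_result`, a model handle, or a checkpoint path
#' @param lam_cfg a [lam_config()]
#' @param train_cfg a [train_config()]
#' @param mask_T Grad-CAM binarization threshold (0-255)
#' @param label_policy class driving mask generation
#' @param warm_start reuse stage-1 backbone weights
#' @param masks optional precomputed list of masks (3D arrays or
#'   `lesion_mask`), bypassing generation
#' @param checkpoint optional path for the trained model
#' @return a `stage_result` (also carries `masks`)
#' @export
train_stage2 <- function(volumes, labels = NULL, stage1, lam_cfg = lam_config(),
                         train_cfg = train_config(), mask_T = 50,
                         label_policy = "true_label", warm_start = TRUE,
                         masks = NULL, checkpoint = NULL) {
  if (is.null(labels)) labels <- vapply(volumes, `[[`, 0L, "label")
  base <- resolve_stage1(stage1)
  if (is.null(masks)) {
    mlist <- batch_generate_masks(base, volumes, label_policy = label_policy,
                                  T = mask_T)
    masks <- lapply(volumes, function(v) mlist[[v$eye_id]]$values)
  } else {
    masks <- lapply(masks, function(m) if (inherits(m, "lesion_mask")) m$values else m)
  }
  set.seed(train_cfg$seed)
  model <- build_lam_network(base$cfg, lam_cfg,
                             backbone = if (warm_start) base else NULL)
  tr <- run_training(model, volumes, labels, train_cfg, masks = masks)
  acc <- model_accuracy(tr$model, volumes, labels, masks = masks)
  if (!is.null(checkpoint)) save_checkpoint(tr$model, checkpoint)
  structure(list(model = tr$model, checkpoint = checkpoint,
                 loss_curve = tr$loss_curve, lr_curve = tr$lr_curve,
                 final_train_acc = acc, seed = train_cfg$seed, masks = masks,
                 config_hash = config_hash(list(base$cfg, lam_cfg, train_cfg))),
            class = "stage_result")
}

#' Two-stage vs baseline comparison on the desk-scale phantom study
#'
#' For each seed: holds out one patient fold, trains the stage-1 baseline on
#' the rest, then the full two-stage attention network under the identical
#' budget, and evaluates both on the held-out patients (test masks come from
#' the stage-1 model under the `predicted` policy, as at inference time).
#'
#' @param volumes study volumes, e.g. [study_phantom_volumes()]
#' @param seeds integer vector; one experiment per seed
#' @param backbone_cfg backbone configuration (default: tiny preset)
#' @param lam_cfg attention configuration
#' @param train_cfg training configuration shared by both arms (its seed is
#'   replaced per experiment)
#' @param holdout_k the held-out split is 1/`holdout_k` of the patients
#' @param mask_T Grad-CAM binarization threshold
#' @return data.frame with seed, baseline_acc, lam_acc on the held-out set
#' @export
two_stage_comparison <- function(volumes, seeds = c(1L, 2L, 3L),
                                 backbone_cfg = tiny_backbone_config(),
                                 lam_cfg = lam_config(),
                                 train_cfg = train_config(epochs = 25L,
                                                          lr = 1e-3,
                                                          step_size = 15L),
                                 holdout_k = 5L, mask_T = 50) {
  patient_ids <- vapply(volumes, `[[`, "", "patient_id")
  labels <- vapply(volumes, `[[`, 0L, "label")
  res <- lapply(seeds, function(s) {
    fold <- make_folds(patient_ids, k = holdout_k, seed = s)[[1L]]
    tr <- which(patient_ids %in% fold$train_patient_ids)
    te <- which(patient_ids %in% fold$test_patient_ids)
    tc <- train_cfg
    tc$seed <- as.integer(s)
    s1 <- train_stage1(volumes[tr], labels[tr], backbone_cfg, tc)
    base_acc <- model_accuracy(s1$model, volumes[te], labels[te])
    s2 <- train_stage2(volumes[tr], labels[tr], s1, lam_cfg, tc, mask_T = mask_T)
    te_masks <- batch_generate_masks(s1$model, volumes[te],
                                     label_policy = "predicted", T = mask_T)
    masks <- lapply(volumes[te], function(v) te_masks[[v$eye_id]]$values)
    lam_acc <- model_accuracy(s2$model, volumes[te], labels[te], masks = masks)
    data.frame(seed = s, baseline_acc = base_acc, lam_acc = lam_acc)
  })
  do.call(rbind, res)
}

#' Softmax probability of the positive (DN) class for one volume
#' @param model model handle
#' @param volume input volume
#' @param mask lesion mask (attention models)
#' @export
predict_prob_dn <- function(model, volume, mask = NULL) {
  softmax_vec(net_forward(model, volume, mask = mask)$scores)[2L]
}
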