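# Evaluation: confusion-matrix metrics, patient-level k-fold splits, ROC/AUC,
# and the cross-validation driver. The positive class is DN (label 1)
# throughout.

#' Confusion counts from predictions and truth
#' @param pred,truth integer vectors of 0/1 labels (1 = DN = positive)
#' @return `confusion_counts`: list with TP, FP, TN, FN
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  structure(list(TP = sum(pred == 1 & truth == 1),
                 FP = sum(pred == 1 & truth == 0),
                 TN = sum(pred == 0 & truth == 0),
                 FN = sum(pred == 0 & truth == 1)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+FN+TN+FP), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP). A metric with a zero denominator is returned as
#' `NA` (undefined), not an error.
#'
#' @param counts a `confusion_counts` or list with TP/FP/TN/FN
#' @return named numeric vector (accuracy, sensitivity, specificity)
#' @export
classification_metrics <- function(counts) {
  n <- counts$TP + counts$FP + counts$TN + counts$FN
  c(accuracy = if (n > 0) (counts$TP + counts$TN) / n else NA_real_,
    sensitivity = if (counts$TP + counts$FN > 0)
      counts$TP / (counts$TP + counts$FN) else NA_real_,
    specificity = if (counts$TN + counts$FP > 0)
      counts$TN / (counts$TN + counts$FP) else NA_real_)
}

#' Patient-level k-fold partition
#'
#' Shuffles the patient ids with the seed and deals them round-robin into k
#' near-equal folds; all volumes of a patient share its fold, so no patient
#' can appear on both sides of a split.
#'
#' @param patients character vector of patient ids (duplicates collapsed)
#' @param k number of folds
#' @param seed integer seed
#' @return list of `fold_split`: `fold_id`, `train_patient_ids`,
#'   `test_patient_ids`
#' @export
make_folds <- function(patients, k = 5L, seed = 1L) {
  ids <- unique(patients)
  if (length(ids) < k) {
    stop("need at least ", k, " patients for ", k, "-fold CV, got ", length(ids))
  }
  shuffled <- with_seed(seed, function() sample(ids))
  fold_of <- rep(seq_len(k), length.out = length(shuffled))
  lapply(seq_len(k), function(f) {
    structure(list(fold_id = f,
                   train_patient_ids = shuffled[fold_of != f],
                   test_patient_ids = shuffled[fold_of == f]),
              class = "fold_split")
  })
}

#' ROC curve and trapezoidal AUC
#'
#' Threshold sweep over all unique scores (higher score = more DN-like);
#' returns the (FPR, TPR) points and the trapezoidal area under them.
#'
#' @param scores numeric scores for the positive class
#' @param labels 0/1 truth
#' @return list with `fpr`, `tpr`, `thresholds`, `auc`
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    return(list(fpr = NA_real_, tpr = NA_real_, thresholds = NA_real_,
                auc = NA_real_))
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  # collapse ties: cumulative counts at each distinct threshold
  cum_tp <- cumsum(l == 1)
  cum_fp <- cumsum(l == 0)
  last <- !duplicated(s, fromLast = TRUE)
  tpr <- c(0, cum_tp[last] / np)
  fpr <- c(0, cum_fp[last] / nn)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, s[last]), auc = auc)
}

# aggregate per-eye DN probabilities to one probability per patient
aggregate_by_patient <- function(probs, patient_ids, labels) {
  agg <- tapply(probs, patient_ids, mean)
  lab <- tapply(labels, patient_ids, function(x) x[1])
  list(prob = as.numeric(agg), label = as.integer(lab),
       patient = names(agg))
}

#' Patient-level k-fold cross-validation of the one- or two-stage pipeline
#'
#' For each fold, trains stage 1 (and, when `lam_cfg` is given, stage 2) on
#' the training patients and evaluates on the held-out patients. Per-eye DN
#' probabilities are averaged per patient before thresholding at 0.5. Reports
#' per-fold and mean accuracy/sensitivity/specificity, and a pooled
#' patient-level ROC/AUC across folds. A fold whose test set is single-class
#' leaves sensitivity or specificity undefined (`NA`); such values are
#' excluded from the mean with a warning.
#'
#' @param volumes list of `oct_volume`s with labels and patient ids
#' @param backbone_cfg a [backbone_config()]
#' @param lam_cfg optional [lam_config()]; when given, each fold runs the full
#'   two-stage procedure and evaluates the attention network (masks for test
#'   volumes come from that fold's stage-1 model under the `predicted` policy)
#' @param train_cfg a [train_config()]
#' @param k number of folds
#' @param seed seed for the fold partition (per-fold training seeds derive
#'   from it)
#' @param mask_T Grad-CAM binarization threshold for stage 2
#' @return `cv_report`: per-fold metrics, mean metrics, pooled ROC, fold
#'   memberships, seed, config hash
#' @export
crossvalidate <- function(volumes, backbone_cfg, lam_cfg = NULL,
                          train_cfg = train_config(), k = 5L, seed = 1L,
                          mask_T = 50) {
  patient_ids <- vapply(volumes, `[[`, "", "patient_id")
  labels <- vapply(volumes, `[[`, 0L, "label")
  folds <- make_folds(patient_ids, k = k, seed = seed)
  per_fold <- list()
  pooled_prob <- c(); pooled_lab <- c()
  for (fs in folds) {
    tr_idx <- which(patient_ids %in% fs$train_patient_ids)
    te_idx <- which(patient_ids %in% fs$test_patient_ids)
    fold_cfg <- train_cfg
    fold_cfg$seed <- (train_cfg$seed + 7919L * fs$fold_id) %% 2147483647L
    s1 <- train_stage1(volumes[tr_idx], labels[tr_idx], backbone_cfg, fold_cfg)
    if (is.null(lam_cfg)) {
      model <- s1$model
      probs <- vapply(te_idx, function(i) predict_prob_dn(model, volumes[[i]]), 0)
    } else {
      s2 <- train_stage2(volumes[tr_idx], labels[tr_idx], s1, lam_cfg, fold_cfg,
                         mask_T = mask_T)
      model <- s2$model
      te_masks <- batch_generate_masks(s1$model, volumes[te_idx],
                                       label_policy = "predicted", T = mask_T)
      probs <- vapply(seq_along(te_idx), function(j) {
        i <- te_idx[j]
        predict_prob_dn(model, volumes[[i]],
                        mask = te_masks[[volumes[[i]]$eye_id]]$values)
      }, 0)
    }
    ag <- aggregate_by_patient(probs, patient_ids[te_idx], labels[te_idx])
    pred <- as.integer(ag$prob >= 0.5)
    cc <- confusion_counts(pred, ag$label)
    per_fold[[fs$fold_id]] <- list(fold_id = fs$fold_id, counts = cc,
                                   metrics = classification_metrics(cc))
    pooled_prob <- c(pooled_prob, ag$prob)
    pooled_lab <- c(pooled_lab, ag$label)
  }
  mm <- sapply(per_fold, `[[`, "metrics")   # 3 x k
  if (anyNA(mm)) {
    warning("some folds have undefined metrics (single-class test set); ",
            "they are excluded from the mean")
  }
  mean_metrics <- rowMeans(mm, na.rm = TRUE)
  roc <- roc_curve(pooled_prob, pooled_lab)
  structure(list(per_fold = per_fold, mean_metrics = mean_metrics,
                 roc = roc, auc = roc$auc,
                 folds = folds, seed = seed,
                 config_hash = config_hash(list(backbone_cfg, lam_cfg,
                                                train_cfg, k, seed))),
            class = "cv_report")
}

#' Write a cross-validation report as JSON
#' @param report a `cv_report`
#' @param path output file
#' @export
write_cv_report <- function(report, path) {
  out <- list(
    mean_metrics = as.list(report$mean_metrics),
    auc = report$auc,
    per_fold = lapply(report$per_fold, function(f) {
      list(fold_id = f$fold_id, counts = unclass(f$counts),
           metrics = as.list(f$metrics))
    }),
    folds = lapply(report$folds, function(f) {
      list(fold_id = f$fold_id, train = f$train_patient_ids,
           test = f$test_patient_ids)
    }),
    seed = report$seed, config_hash = report$config_hash)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
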