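# Metrics, patient-level folds, ROC/AUC, cross-validation driver.

test_that("metric formulas reproduce hand-computed values", {
  cc <- list(TP = 8, FN = 2, TN = 9, FP = 1)
  m <- classification_metrics(cc)
  expect_equal(unname(m), c(0.85, 0.80, 0.90))
  perfect <- classification_metrics(list(TP = 5, FN = 0, TN = 7, FP = 0))
  expect_equal(unname(perfect), c(1, 1, 1))
})

test_that("swapping the positive class swaps sensitivity and specificity", {
  set.seed(50)
  for (i in 1:20) {
    pred <- rbinom(30, 1, 0.5); truth <- rbinom(30, 1, 0.5)
    m1 <- classification_metrics(confusion_counts(pred, truth))
    m2 <- classification_metrics(confusion_counts(1 - pred, 1 - truth))
    expect_equal(m1[["accuracy"]], m2[["accuracy"]])
    expect_equal(m1[["sensitivity"]], m2[["specificity"]])
    expect_equal(m1[["specificity"]], m2[["sensitivity"]])
  }
})

test_that("zero denominators yield NA markers, not errors", {
  m <- classification_metrics(list(TP = 0, FN = 0, TN = 3, FP = 1))
  expect_true(is.na(m[["sensitivity"]]))
  expect_equal(m[["specificity"]], 0.75)
})

test_that("patient folds partition the cohort and are seed-reproducible", {
  pts <- sprintf("P%02d", 1:10)
  f <- make_folds(pts, k = 5, seed = 2)
  expect_length(f, 5)
  expect_true(all(vapply(f, function(x) length(x$test_patient_ids), 0L) == 2L))
  test_union <- sort(unlist(lapply(f, `[[`, "test_patient_ids")))
  expect_equal(test_union, sort(pts))               # union == all, no overlap
  for (x in f) {
    expect_length(intersect(x$train_patient_ids, x$test_patient_ids), 0)
    expect_setequal(c(x$train_patient_ids, x$test_patient_ids), pts)
  }
  expect_identical(make_folds(pts, 5, seed = 2), f)
  expect_false(identical(make_folds(pts, 5, seed = 3), f))
  expect_error(make_folds(pts[1:3], k = 5), "at least 5")
  # duplicated patient ids (several eyes) collapse to the patient level
  f2 <- make_folds(rep(pts, each = 2), k = 5, seed = 1)
  expect_equal(sort(unlist(lapply(f2, `[[`, "test_patient_ids"))), sort(pts))
})

test_that("ROC hits its limits and AUC is invariant to monotone transforms", {
  labels <- c(0, 0, 1, 1, 0, 1)
  perfect <- c(0.1, 0.2, 0.8, 0.9, 0.15, 0.95)
  expect_equal(roc_curve(perfect, labels)$auc, 1.0)
  expect_equal(roc_curve(rep(0.5, 6), labels)$auc, 0.5)
  set.seed(51)
  sc <- runif(40); lb <- rbinom(40, 1, 0.5)
  a1 <- roc_curve(sc, lb)$auc
  expect_equal(roc_curve(qlogis(sc), lb)$auc, a1)
  expect_equal(roc_curve(sc^3, lb)$auc, a1)
  expect_true(is.na(roc_curve(sc, rep(1, 40))$auc))
})

test_that("trapezoidal AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(52)
  sc <- runif(60); lb <- rbinom(60, 1, 0.4)
  ours <- roc_curve(sc, lb)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("per-eye probabilities aggregate to one decision per patient", {
  ag <- octlan:::aggregate_by_patient(c(0.9, 0.3, 0.2), c("A", "A", "B"),
                                      c(1, 1, 0))
  expect_equal(ag$prob[ag$patient == "A"], 0.6)
  expect_equal(ag$label, c(1L, 0L))
})

test_that("cross-validation on separable phantoms reaches perfect mean accuracy", {
  # noise-free phantoms with a large central lesion: perfectly separable
  sp <- phantom_spec(width = 96, height = 96, n_slices = 64, n_layers = 3,
                     lesion_radius = 14, noise_sigma = 0, seed = 60)
  ds <- generate_dataset(10, 0.5, sp, seed = 60)
  vols <- preprocess_dataset(ds, small_cfg())
  tc <- train_config(epochs = 20, lr = 1e-3, step_size = 15, seed = 1)
  rep <- suppressWarnings(
    crossvalidate(vols, tiny_backbone_config(), NULL, tc, k = 5, seed = 4))
  expect_s3_class(rep, "cv_report")
  expect_length(rep$per_fold, 5)
  expect_equal(rep$mean_metrics[["accuracy"]], 1.0)
  expect_equal(rep$auc, 1.0)
  p <- withr::local_tempfile(fileext = ".json")
  write_cv_report(rep, p)
  js <- jsonlite::read_json(p)
  expect_equal(js$mean_metrics$accuracy, 1.0)
  expect_length(js$folds, 5)
})

test_that("randomly permuted labels drop cross-validated accuracy to chance", {
  vols <- study_phantom_volumes(10, 0.5, seed = 61)
  set.seed(62)
  perm <- sample(vapply(vols, `[[`, 0L, "label"))
  vols <- lapply(seq_along(vols), function(i) {
    v <- vols[[i]]; v$label <- perm[i]; v
  })
  tc <- train_config(epochs = 20, lr = 1e-3, step_size = 15, seed = 1)
  rep <- suppressWarnings(
    crossvalidate(vols, tiny_backbone_config(), NULL, tc, k = 5, seed = 4))
  # chance level for 10 balanced patient-level decisions
  expect_gte(rep$mean_metrics[["accuracy"]], 0.2)
  expect_lte(rep$mean_metrics[["accuracy"]], 0.8)
})
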