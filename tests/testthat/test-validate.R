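test_that("strong folds never split a patient; weak folds do", {
  man <- toy_manifest(n_patients = 8, images_per_patient = 3)
  for (seed in 1:20) {
    sp <- make_folds(man, "strong", 3, seed = seed)
    pats <- lapply(sp$folds, function(f) unique(man$patient_id[f]))
    expect_length(Reduce(intersect, pats), 0)
    expect_equal(sort(unlist(sp$folds)), seq_len(nrow(man)))
  }
  # weak mode on a 2-patient dataset must split someone across folds
  man2 <- toy_manifest(n_patients = 2, images_per_patient = 6,
                       classes = c("NORMAL", "CA"))
  sp2 <- make_folds(man2, "weak", 3, seed = 1)
  pats2 <- lapply(sp2$folds, function(f) unique(man2$patient_id[f]))
  expect_gt(length(unlist(pats2)), length(unique(man2$patient_id)))
  # reproducible from the seed
  expect_identical(make_folds(man, "strong", 3, seed = 9)$folds,
                   make_folds(man, "strong", 3, seed = 9)$folds)
})

test_that("a balanced 12-image manifest splits one image per class per fold", {
  man <- toy_manifest(n_patients = 12, images_per_patient = 1)
  for (mode in c("strong", "weak")) {
    sp <- make_folds(man, mode, 3, seed = 4)
    for (f in sp$folds)
      expect_equal(unname(table(man$label[f])), rep(1L, 4), ignore_attr = TRUE)
  }
})

test_that("infeasible strong splits name the offending patients", {
  man <- toy_manifest(n_patients = 4, images_per_patient = 3,
                      classes = c("NORMAL", "HP", "TA_LG", "CA"))
  # patient P01 owns every NORMAL image
  expect_error(make_folds(man, "strong", 3, seed = 1),
               "split error.*P01")
  expect_error(make_folds(toy_manifest(4, 1), "weak", 3),
               "fewer images than folds")
})

test_that("binary collapse matches the arithmetic oracle", {
  # confusion [[TP=3, FN=1], [FP=1, TN=3]]
  truth <- c(rep("CA", 4), rep("NORMAL", 4))
  pred <- c("CA", "CA", "CA", "NORMAL", "CA", "NORMAL", "NORMAL", "NORMAL")
  s <- summarize_binary(pred, truth, positive_set = "CA")
  expect_equal(unname(s), c(6 / 8, 0.75, 0.75, 0.75))
  # all correct
  expect_equal(unname(summarize_binary(truth, truth, "CA")), rep(1, 4))
  # a TA_LG sample predicted HP is a correct negative when positives = {CA}
  s2 <- summarize_binary(c("HP", "CA"), c("TA_LG", "CA"), "CA")
  expect_equal(unname(s2["accuracy"]), 1)
  # positives = {CA, TA_LG}: the same prediction is now a false negative
  s3 <- summarize_binary(c("HP", "CA"), c("TA_LG", "CA"), c("CA", "TA_LG"))
  expect_equal(unname(s3["sensitivity"]), 0.5)
})

test_that("ROC follows the trapezoid rule and its symmetries", {
  pos <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(roc_curve(c(6:10, 1:5), pos)$auc, 1)
  set.seed(61)
  score <- runif(40)
  truth <- runif(40) > 0.5
  a <- roc_curve(score, truth)$auc
  expect_equal(roc_curve(-score, truth)$auc, 1 - a, tolerance = 1e-12)
  # independent oracle: pROC's trapezoid AUC
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE))),
               tolerance = 1e-10)
  expect_error(roc_curve(score, rep(TRUE, 40)), "undefined-ROC")

  # the two positive-class conventions
  cls <- c("CA", "HP", "NORMAL", "TA_LG")
  set.seed(62)
  truth4 <- sample(cls, 60, replace = TRUE)
  pr <- matrix(runif(240), 60, 4, dimnames = list(NULL, cls))
  pr <- pr / rowSums(pr)
  rc <- roc_curves(pr, truth4)
  expect_named(rc, c("ca", "ta_lg"))
  # ROC-2 excludes CA samples entirely
  expect_equal(length(rc$ta_lg$fpr) <= sum(truth4 != "CA") + 1, TRUE)
})

test_that("cross-validated pipeline separates designed classes", {
  cfg <- synth_config(n_patients = 8, images_per_patient = 3,
                      class_set = c("NORMAL", "CA"), H = 48, W = 48,
                      vs_wavelengths_nm = c(470, 490),
                      irs_wavelengths_nm = c(1150, 1170),
                      texture_scale = 12, seed = 63)
  ds <- generate_dataset(cfg)
  fx <- extract_dataset_features(ds$manifest, ds$cubes,
                                 cfg = descriptor_config(tamura_kmax = 4L),
                                 descriptors = c("glcm", "histogram"))
  sp <- make_folds(ds$manifest, "strong", 3, seed = 2)
  rep <- run_cv(fx$features, fx$info, sp, fx$fold_of,
                ensemble_config(n_components = 8, seed = 2),
                task = "two_class")
  expect_gt(rep$tile_accuracy, 0.8)
  expect_equal(sum(rep$confusion), nrow(ds$manifest))
  expect_equal(rep$tile_accuracy, sum(diag(rep$confusion)) / sum(rep$confusion))
  expect_true(all(abs(rowSums(rep$probabilities) - 1) < 1e-6))
  # the concatenated strategy runs the same protocol
  rep2 <- run_cv(fx$features, fx$info, sp, fx$fold_of,
                 ensemble_config(reduction = "none", seed = 2),
                 task = "two_class", strategy = "concatenated")
  expect_gt(rep2$tile_accuracy, 0.7)
})

test_that("four-class task reports a full confusion matrix and both ROCs", {
  cfg <- synth_config(n_patients = 8, images_per_patient = 3, H = 48, W = 48,
                      vs_wavelengths_nm = c(470, 490),
                      irs_wavelengths_nm = c(1150, 1170),
                      texture_scale = 12, noise_sd = 0.02, seed = 64)
  ds <- generate_dataset(cfg)
  fx <- extract_dataset_features(ds$manifest, ds$cubes,
                                 cfg = descriptor_config(tamura_kmax = 4L),
                                 descriptors = c("glcm", "histogram", "perception"))
  sp <- make_folds(ds$manifest, "strong", 2, seed = 3)
  rep <- run_cv(fx$features, fx$info, sp, fx$fold_of,
                ensemble_config(n_components = 8, seed = 3),
                task = "four_class")
  expect_equal(dim(rep$confusion), c(4L, 4L))
  expect_gt(rep$tile_accuracy, 0.5)  # far above the 25% chance level
  rc <- roc_curves(rep$probabilities, rep$truth)
  expect_gt(rc$ca$auc, 0.8)
  bin <- summarize_binary(rep$predicted, rep$truth, "CA")
  expect_true(all(bin >= 0 & bin <= 1))
})
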