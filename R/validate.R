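#' Build cross-validation folds at patient or image level
#'
#' Strong mode splits whole patients: all images of a patient (across all of
#' their slides) land in a single fold, assigned by a seeded greedy pass that
#' keeps per-fold class counts as balanced as the patient structure allows.
#' Weak mode assigns images to folds stratified by class only, so one
#' patient's images may span training and test folds.
#'
#' @param manifest an `ms_manifest` (one row per image).
#' @param mode `"strong"` (patient-level) or `"weak"` (image-level).
#' @param n_folds number of folds (default 3).
#' @param seed integer seed making the assignment reproducible.
#' @return object of class `fold_split`: list with `mode`, `folds` (list of
#'   integer row-index vectors partitioning the manifest), `seed`.
#' @export
make_folds <- function(manifest, mode = c("strong", "weak"), n_folds = 3L,
                       seed = 1L) {
  mode <- match.arg(mode)
  cls <- attr(manifest, "class_set") %||% sort(unique(manifest$label))
  cnt <- table(factor(manifest$label, cls))
  if (any(cnt < n_folds))
    stop("split error: class(es) with fewer images than folds: ",
         paste(cls[cnt < n_folds], collapse = ", "))
  assign_f <- if (mode == "weak") {
    with_local_seed(seed, stratified_folds(factor(manifest$label, cls), n_folds))
  } else {
    offenders <- vapply(cls, function(cl) {
      own <- table(manifest$patient_id[manifest$label == cl])
      names(own)[own == cnt[cl]][1] %||% NA_character_
    }, character(1))
    bad <- !is.na(offenders) & n_folds > 1L
    if (any(bad))
      stop("split error: patient(s) owning every image of a class: ",
           paste(sprintf("%s (%s)", offenders[bad], cls[bad]), collapse = ", "))
    with_local_seed(seed, strong_assign(manifest, cls, n_folds))
  }
  folds <- lapply(seq_len(n_folds), function(f) which(assign_f == f))
  structure(list(mode = mode, folds = folds, seed = as.integer(seed),
                 n_folds = as.integer(n_folds)),
            class = "fold_split")
}

# greedy patient assignment: patients in random order, each to the fold
# where adding them least worsens class-count imbalance (then smallest fold)
strong_assign <- function(manifest, cls, k) {
  pats <- sample(unique(manifest$patient_id))
  counts <- matrix(0, k, length(cls), dimnames = list(NULL, cls))
  pat_fold <- stats::setNames(integer(length(pats)), pats)
  for (p in pats) {
    add <- table(factor(manifest$label[manifest$patient_id == p], cls))
    score <- vapply(seq_len(k), function(f) {
      trial <- counts
      trial[f, ] <- trial[f, ] + add
      sum(apply(trial, 2, function(col) max(col) - min(col)))
    }, numeric(1))
    f <- which(score == min(score))
    if (length(f) > 1L) f <- f[which.min(rowSums(counts)[f])]
    counts[f, ] <- counts[f, ] + add
    pat_fold[p] <- f
  }
  unname(pat_fold[manifest$patient_id])
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("fold_split: %s mode, %d folds of sizes %s (seed %d)\n",
              x$mode, x$n_folds,
              paste(lengths(x$folds), collapse = "/"), x$seed))
  invisible(x)
}

#' Binary collapse of multi-class predictions
#'
#' Collapses predictions and truth to positive/negative according to
#' `positive_set` (e.g. carcinoma only, or carcinoma together with
#' low-grade tubular adenoma) and computes accuracy, sensitivity,
#' specificity and F1.
#'
#' @param predicted,truth class label vectors of equal length.
#' @param positive_set character vector of classes counted as positive.
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `f1`.
#' @export
summarize_binary <- function(predicted, truth, positive_set) {
  pp <- predicted %in% positive_set
  tp0 <- truth %in% positive_set
  tp <- sum(pp & tp0); tn <- sum(!pp & !tp0)
  fp <- sum(pp & !tp0); fn <- sum(!pp & tp0)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(accuracy = (tp + tn) / length(truth),
    sensitivity = sens,
    specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
    f1 = if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0)
}

#' Receiver operating characteristic by threshold sweep
#'
#' Points are the (false positive rate, true positive rate) pairs obtained
#' by thresholding the score at every observed value; the area under the
#' curve is computed by the trapezoid rule.
#'
#' @param score numeric vector, larger = more positive.
#' @param positive logical vector, truth.
#' @return object of class `roc_curve`: list with `fpr`, `tpr`, `auc`.
#' @export
roc_curve <- function(score, positive) {
  if (!any(positive) || all(positive))
    stop("undefined-ROC error: need both positive and negative samples")
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; pos <- positive[ord]
  ends <- c(which(diff(s) != 0), length(s))  # one point per distinct score
  tpr <- c(0, cumsum(pos)[ends] / sum(pos))
  fpr <- c(0, cumsum(!pos)[ends] / sum(!pos))
  structure(list(fpr = fpr, tpr = tpr,
                 auc = sum(diff(fpr) * (utils::head(tpr, -1) +
                                          utils::tail(tpr, -1)) / 2)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlab = "false positive rate",
       ylab = "true positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' The two positive-class ROC conventions
#'
#' ROC-1 treats carcinoma (`"CA"`) as positive against every other class.
#' ROC-2 removes the carcinoma samples and treats low-grade tubular adenoma
#' (`"TA_LG"`) as positive among the remainder.
#'
#' @param probabilities samples x classes matrix, columns named by class.
#' @param truth class labels.
#' @param ca,ta_lg names of the carcinoma and adenoma classes.
#' @return list of two `roc_curve` objects, `ca` and `ta_lg`.
#' @export
roc_curves <- function(probabilities, truth, ca = "CA", ta_lg = "TA_LG") {
  keep <- truth != ca
  list(ca = roc_curve(probabilities[, ca], truth == ca),
       ta_lg = roc_curve(probabilities[keep, ta_lg], truth[keep] == ta_lg))
}

#' Cross-validated evaluation of the full pipeline
#'
#' For each fold the full pipeline (standardize, reduce, stacked ensemble or
#' concatenated classifier) is fitted on the training folds and evaluated on
#' the held-out fold. The two-class task restricts the data to the normal
#' and carcinoma classes before splitting out features. Tile predictions are
#' aggregated to whole-image labels per [aggregate_tiles()].
#'
#' @param features named list of descriptor matrices covering every manifest
#'   row (tiles).
#' @param tile_info data.frame with one row per feature row: columns `label`,
#'   `parent_image_id` (and anything else); typically built alongside
#'   feature extraction.
#' @param split a `fold_split` built on the same rows via their parent
#'   image's manifest row (`fold_of`: manifest row index per tile).
#' @param fold_of integer vector mapping each feature row to a manifest row
#'   index 1..n_images (identity when samples are whole images).
#' @param cfg an [ensemble_config()].
#' @param task `"four_class"` or `"two_class"`; the two-class task keeps
#'   only `classes_two`.
#' @param classes_two the two classes of the easy task.
#' @param strategy `"ensemble"` or `"concatenated"`.
#' @return object of class `cv_report`: per-fold and mean +/- sd metrics,
#'   pooled confusion matrix, tile- and image-level accuracies, pooled
#'   predictions.
#' @export
run_cv <- function(features, tile_info, split, fold_of = NULL,
                   cfg = ensemble_config(),
                   task = c("four_class", "two_class"),
                   classes_two = c("NORMAL", "CA"),
                   strategy = c("ensemble", "concatenated")) {
  task <- match.arg(task)
  strategy <- match.arg(strategy)
  features <- lapply(features, as.matrix)
  n <- nrow(features[[1]])
  fold_of <- fold_of %||% seq_len(n)
  keep <- rep(TRUE, n)
  if (task == "two_class") keep <- tile_info$label %in% classes_two
  cls <- sort(unique(tile_info$label[keep]))

  fold_id <- integer(n)
  for (f in seq_along(split$folds)) fold_id[fold_of %in% split$folds[[f]]] <- f
  if (any(fold_id[keep] == 0)) stop("split error: split does not cover the data")

  per_fold <- list()
  pooled_pred <- character(n); pooled_prob <- matrix(NA_real_, n, length(cls),
                                                     dimnames = list(NULL, cls))
  agg_pred <- character(n)
  for (f in seq_along(split$folds)) {
    tr <- keep & fold_id != f
    te <- keep & fold_id == f
    if (!any(te)) next
    trx <- lapply(features, function(m) m[tr, , drop = FALSE])
    tex <- lapply(features, function(m) m[te, , drop = FALSE])
    model <- if (strategy == "ensemble") ms_ensemble(trx, tile_info$label[tr], cfg)
    else train_concatenated(trx, tile_info$label[tr], cfg)
    pred <- predict(model, tex)
    pooled_pred[te] <- pred$class
    pooled_prob[te, model$class_order] <- pred$probabilities
    agg <- aggregate_tiles(pred$class, pred$probabilities,
                           tile_info$parent_image_id[te], model$class_order)
    agg_pred[te] <- agg$tile_label
    per_fold[[f]] <- c(tile_accuracy = mean(pred$class == tile_info$label[te]),
                       image_accuracy = mean(agg$tile_label == tile_info$label[te]))
  }
  pf <- do.call(rbind, per_fold)
  cm <- table(truth = factor(tile_info$label[keep], cls),
              predicted = factor(pooled_pred[keep], cls))
  structure(list(task = task, strategy = strategy, mode = split$mode,
                 classes = cls,
                 per_fold = pf,
                 mean = colMeans(pf), sd = apply(pf, 2, stats::sd),
                 confusion = cm,
                 tile_accuracy = mean(pooled_pred[keep] == tile_info$label[keep]),
                 image_accuracy = mean(agg_pred[keep] == tile_info$label[keep]),
                 predicted = pooled_pred[keep],
                 aggregated = agg_pred[keep],
                 probabilities = pooled_prob[keep, , drop = FALSE],
                 truth = tile_info$label[keep]),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %s, %s strategy, %s cross-validation\n",
              x$task, x$strategy, x$mode))
  cat(sprintf("  tile accuracy  %.1f%% (per fold mean %.1f +/- %.1f)\n",
              100 * x$tile_accuracy, 100 * x$mean["tile_accuracy"],
              100 * x$sd["tile_accuracy"]))
  cat(sprintf("  image accuracy %.1f%% after tile aggregation\n",
              100 * x$image_accuracy))
  cat("  confusion matrix (tiles):\n")
  print(x$confusion)
  invisible(x)
}
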