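#' Ensemble pipeline configuration
#'
#' @param reduction `"global_pca"` or `"none"`; per-descriptor reduction in
#'   the ensemble path, post-concatenation reduction in the concatenated
#'   path.
#' @param n_components PCA components per descriptor (capped at
#'   min(n - 1, d) at fit time).
#' @param kernel,cost base-classifier kernel and soft-margin cost
#'   (passed to [e1071::svm()]).
#' @param cross_fit_folds internal folds used to produce out-of-fold base
#'   probabilities for meta-classifier training.
#' @param seed seed for the internal cross-fitting split.
#' @return list of class `ensemble_config`.
#' @export
ensemble_config <- function(reduction = "global_pca", n_components = 64L,
                            kernel = "radial", cost = 1,
                            cross_fit_folds = 3L, seed = 1L) {
  stopifnot(reduction %in% c("global_pca", "none"))
  structure(list(reduction = reduction, n_components = as.integer(n_components),
                 kernel = kernel, cost = cost,
                 cross_fit_folds = as.integer(cross_fit_folds),
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Fit the stacked texture-descriptor ensemble
#'
#' Each texture descriptor's feature block is learned by its own
#' probabilistic classifier: standardize with training statistics, reduce,
#' fit a soft-margin kernel SVM, and turn its one-vs-one decision margins
#' into class probabilities by a softmax. A linear meta-classifier
#' ("weight allocation", a lightly ridged multinomial logistic model) is
#' then trained on the concatenated class probabilities of all base
#' classifiers. So that the meta input matches its test-time distribution,
#' the training probabilities are produced out-of-fold by internal
#' cross-fitting, never in-sample.
#'
#' @param features named list, one samples x d matrix per descriptor; all
#'   matrices must cover the same samples with no missing descriptor.
#' @param labels class labels, length n (>= 2 classes).
#' @param cfg an [ensemble_config()].
#' @return object of class `ms_ensemble` with elements `class_order`,
#'   `base` (per-descriptor standardizer, reducer and classifier) and
#'   `meta`.
#' @export
ms_ensemble <- function(features, labels, cfg = ensemble_config()) {
  features <- check_feature_map(features, labels)
  labels <- as.character(labels)
  class_order <- sort(unique(labels))
  if (length(class_order) < 2) stop("data error: need >= 2 classes")
  y <- factor(labels, levels = class_order)

  base <- lapply(features, fit_base, y = y, cfg = cfg)
  names(base) <- names(features)

  # out-of-fold base probabilities for the meta classifier
  n <- length(labels)
  folds <- with_local_seed(cfg$seed,
                           stratified_folds(y, cfg$cross_fit_folds))
  meta_x <- matrix(0, n, length(features) * length(class_order))
  for (f in seq_len(cfg$cross_fit_folds)) {
    hold <- folds == f
    for (di in seq_along(features)) {
      bf <- fit_base(features[[di]][!hold, , drop = FALSE], y[!hold], cfg)
      p <- base_probabilities(bf, features[[di]][hold, , drop = FALSE],
                              class_order)
      cols <- (di - 1L) * length(class_order) + seq_along(class_order)
      meta_x[hold, cols] <- p
    }
  }
  meta <- fit_meta(meta_x, y)
  structure(list(class_order = class_order, base = base, meta = meta,
                 descriptors = names(features), cfg = cfg,
                 n_train = n),
            class = "ms_ensemble")
}

check_feature_map <- function(features, labels) {
  if (is.null(names(features)) || any(names(features) == ""))
    stop("data error: features must be a named list of descriptor matrices")
  features <- lapply(features, as.matrix)
  n <- unique(vapply(features, nrow, integer(1)))
  if (length(n) != 1 || n != length(labels))
    stop("data error: descriptor matrices must all have one row per sample")
  features
}

# standardize -> reduce -> probabilistic SVM for one descriptor
fit_base <- function(x, y, cfg) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
  reducer <- NULL
  if (cfg$reduction == "global_pca") {
    k <- min(cfg$n_components, nrow(xs) - 1L, ncol(xs))
    reducer <- fit_global_pca(xs, k)
    xs <- predict(reducer, xs)
  }
  model <- with_local_seed(cfg$seed,
    e1071::svm(xs, y, kernel = cfg$kernel, cost = cfg$cost, scale = FALSE))
  list(center = mu, scale = sdv, reducer = reducer, model = model)
}

# class probabilities as a softmax over one-vs-one decision-value margins.
# libsvm's own probability mode refits a sigmoid by internal CV, which can
# invert on small training sets; the plain margin softmax is deterministic
# and order-faithful, and the meta classifier relearns its scaling anyway.
base_probabilities <- function(bf, x, class_order) {
  xs <- sweep(sweep(as.matrix(x), 2, bf$center), 2, bf$scale, `/`)
  if (!is.null(bf$reducer)) xs <- predict(bf$reducer, xs)
  dv <- attr(stats::predict(bf$model, xs, decision.values = TRUE),
             "decision.values")
  score <- matrix(0, nrow(xs), length(class_order),
                  dimnames = list(NULL, class_order))
  for (k in seq_len(ncol(dv))) {
    pair <- strsplit(colnames(dv)[k], "/", fixed = TRUE)[[1]]
    score[, pair[1]] <- score[, pair[1]] + dv[, k]
    score[, pair[2]] <- score[, pair[2]] - dv[, k]
  }
  p <- exp(score - apply(score, 1, max))
  p / rowSums(p)
}

# linear meta-classifier ("weight allocation") over concatenated base
# probabilities: a lightly ridged multinomial logistic model. A linear
# probabilistic model is used here rather than a Platt-calibrated SVM
# because sigmoid calibration refitted on the small stacked training sets
# can invert, while the likelihood fit is stable and its argmax always
# agrees with the reported probabilities.
fit_meta <- function(meta_x, y) {
  df <- as.data.frame(meta_x)
  names(df) <- paste0("m", seq_len(ncol(meta_x)))
  df$.y <- y
  nnet::multinom(.y ~ ., df, trace = FALSE, decay = 1e-3, maxit = 500)
}

meta_probabilities <- function(meta, meta_x, class_order) {
  df <- as.data.frame(meta_x)
  names(df) <- paste0("m", seq_len(ncol(meta_x)))
  p <- stats::predict(meta, df, type = "probs")
  if (length(class_order) == 2L) {
    # binomial fit returns P(second level)
    p <- cbind(1 - p, p)
    colnames(p) <- meta$lev
  }
  if (is.null(dim(p))) p <- matrix(p, 1, dimnames = list(NULL, meta$lev))
  p <- p[, class_order, drop = FALSE]
  rownames(p) <- NULL
  p / rowSums(p)
}

# stratified fold labels 1..k, as equal as possible within each class
stratified_folds <- function(y, k) {
  f <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    f[idx] <- rep_len(seq_len(k), length(idx))
  }
  f
}

#' Predict classes and probabilities from a fitted ensemble
#'
#' @param object an `ms_ensemble`.
#' @param newdata named list of descriptor matrices matching the training
#'   layout.
#' @param ... unused.
#' @return object of class `ms_predictions`: list with `class` (predicted
#'   labels; argmax with ties resolved to the earliest class in
#'   `class_order`), `probabilities` (n x C matrix) and `per_descriptor`
#'   (list of base-probability matrices).
#' @export
predict.ms_ensemble <- function(object, newdata, ...) {
  newdata <- lapply(newdata, as.matrix)
  miss <- setdiff(object$descriptors, names(newdata))
  if (length(miss))
    stop("data error: missing descriptor(s): ", paste(miss, collapse = ", "))
  C <- length(object$class_order)
  per <- list()
  n <- nrow(newdata[[object$descriptors[1]]])
  meta_x <- matrix(0, n, length(object$descriptors) * C)
  for (di in seq_along(object$descriptors)) {
    d <- object$descriptors[di]
    if (ncol(newdata[[d]]) != length(object$base[[d]]$center))
      stop("contract error: feature length mismatch for ", d)
    p <- base_probabilities(object$base[[d]], newdata[[d]],
                            object$class_order)
    per[[d]] <- p
    meta_x[, (di - 1L) * C + seq_len(C)] <- p
  }
  pr <- meta_probabilities(object$meta, meta_x, object$class_order)
  ms_predictions(pr, object$class_order, per)
}

ms_predictions <- function(probabilities, class_order, per_descriptor = NULL) {
  cls <- class_order[apply(probabilities, 1, which.max)]  # earliest on ties
  structure(list(class = cls, probabilities = probabilities,
                 class_order = class_order,
                 per_descriptor = per_descriptor),
            class = "ms_predictions")
}

#' @export
print.ms_predictions <- function(x, ...) {
  cat("ms_predictions for", length(x$class), "samples\n")
  print(table(x$class))
  invisible(x)
}

#' @export
print.ms_ensemble <- function(x, ...) {
  cat(sprintf("ms_ensemble: %d descriptors (%s), %d classes, %d training samples\n",
              length(x$descriptors), paste(x$descriptors, collapse = ", "),
              length(x$class_order), x$n_train))
  invisible(x)
}

#' @export
summary.ms_ensemble <- function(object, ...) {
  cat("Stacked texture-descriptor ensemble\n")
  print(object)
  cat("  classes:", paste(object$class_order, collapse = ", "), "\n")
  cat("  meta input width:",
      length(object$descriptors) * length(object$class_order), "\n")
  w <- meta_weight_norms(object)
  cat("  meta weight L2 norm per descriptor block:\n")
  print(round(w, 4))
  invisible(object)
}

#' L2 norm of the meta-classifier weights per descriptor block
#'
#' The linear meta-classifier's primal weights (summed over its one-vs-one
#' binary machines) measure how much each base classifier's probability
#' block contributes to the final decision.
#'
#' @param object an `ms_ensemble`.
#' @return named numeric vector, one norm per descriptor.
#' @export
meta_weight_norms <- function(object) {
  W <- stats::coef(object$meta)
  if (is.null(dim(W))) W <- matrix(W, 1)
  W <- W[, -1, drop = FALSE]  # drop intercept
  C <- length(object$class_order)
  norms <- vapply(seq_along(object$descriptors), function(di) {
    cols <- (di - 1L) * C + seq_len(C)
    sqrt(sum(W[, cols]^2))
  }, numeric(1))
  names(norms) <- object$descriptors
  norms
}

#' Fit the concatenated-feature baseline classifier
#'
#' The comparison strategy to the ensemble: all descriptor blocks are
#' concatenated into one long vector, reduced after concatenation, and
#' learned by a single probability-calibrated SVM.
#'
#' @inheritParams ms_ensemble
#' @return object of class `ms_concat`.
#' @export
train_concatenated <- function(features, labels, cfg = ensemble_config()) {
  features <- check_feature_map(features, labels)
  labels <- as.character(labels)
  class_order <- sort(unique(labels))
  y <- factor(labels, levels = class_order)
  X <- do.call(cbind, features)
  widths <- vapply(features, ncol, integer(1))
  base <- fit_base(X, y, cfg)
  structure(list(class_order = class_order, base = base, widths = widths,
                 descriptors = names(features), cfg = cfg),
            class = "ms_concat")
}

#' @export
predict.ms_concat <- function(object, newdata, ...) {
  newdata <- lapply(newdata, as.matrix)
  X <- do.call(cbind, newdata[object$descriptors])
  if (ncol(X) != length(object$base$center))
    stop("contract error: feature length mismatch")
  pr <- base_probabilities(object$base, X, object$class_order)
  ms_predictions(pr, object$class_order)
}

#' @export
print.ms_concat <- function(x, ...) {
  cat(sprintf("ms_concat: single classifier on %d concatenated features\n",
              sum(x$widths)))
  invisible(x)
}

#' Aggregate tile predictions to whole-image labels
#'
#' All tiles of one whole image receive the image's modal predicted class.
#' When several classes tie for the mode, the tied class with the highest
#' mean predicted probability (over the image's tiles) wins; any remaining
#' tie resolves to the earliest class in `class_order`.
#'
#' @param predicted_class character vector of tile predictions.
#' @param probabilities tiles x classes probability matrix (columns in
#'   `class_order`).
#' @param parent_image_id whole-image identifier per tile.
#' @param class_order ordered class names.
#' @return list with `image_label` (named by image) and `tile_label`
#'   (per-tile labels after aggregation, aligned with the input).
#' @export
aggregate_tiles <- function(predicted_class, probabilities, parent_image_id,
                            class_order) {
  stopifnot(length(predicted_class) == nrow(probabilities),
            length(parent_image_id) == length(predicted_class))
  img <- unique(parent_image_id)
  lab <- vapply(img, function(id) {
    sel <- parent_image_id == id
    votes <- table(factor(predicted_class[sel], levels = class_order))
    top <- class_order[votes == max(votes)]
    if (length(top) > 1L) {
      mp <- colMeans(probabilities[sel, , drop = FALSE])[top]
      top <- top[mp == max(mp)]
    }
    top[1L]
  }, character(1))
  names(lab) <- img
  list(image_label = lab, tile_label = unname(lab[parent_image_id]))
}
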