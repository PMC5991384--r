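#' Pool centre patches of each band across samples
#'
#' Builds the pixels-by-bands data matrix used by band selection: a patch of
#' size `patch` is cut from the centre of every band of every cube and the
#' patch pixels of all samples are stacked, giving one pooled column per
#' band.
#'
#' @param samples list of `spectral_cube` objects with identical band layout.
#' @param patch integer length-2 patch size (rows, cols), default 64 x 64.
#' @return object of class `band_matrix_set`: list with `P` (pooled pixels x
#'   bands matrix), `source_patch`, `m` (number of samples), `wavelengths_nm`
#'   and `spectrum_tags`.
#' @export
band_matrix_set <- function(samples, patch = c(64, 64)) {
  stopifnot(length(samples) >= 1, all(vapply(samples, inherits, TRUE,
                                             "spectral_cube")))
  b <- n_bands(samples[[1]])
  d1 <- dim(samples[[1]]$pixels)
  if (d1[1] < patch[1] || d1[2] < patch[2])
    stop("config error: ", patch[1], "x", patch[2],
         " patch larger than the ", d1[1], "x", d1[2], " image")
  blocks <- lapply(samples, function(s) {
    d <- dim(s$pixels)
    if (d[3] != b) stop("format error: cubes have differing band counts")
    r0 <- (d[1] - patch[1]) %/% 2L
    c0 <- (d[2] - patch[2]) %/% 2L
    px <- s$pixels[(r0 + 1L):(r0 + patch[1]),
                   (c0 + 1L):(c0 + patch[2]), , drop = FALSE]
    matrix(px, patch[1] * patch[2], b)
  })
  structure(list(P = do.call(rbind, blocks),
                 source_patch = as.integer(patch), m = length(samples),
                 wavelengths_nm = samples[[1]]$wavelengths_nm,
                 spectrum_tags = samples[[1]]$spectrum_tags),
            class = "band_matrix_set")
}

#' Screen adjacent bands by spectral correlation
#'
#' Computes Pearson correlations between each pair of adjacent bands, pooled
#' over centre patches of all samples, and flags pairs whose correlation
#' falls below `threshold`. The pair straddling the VS/IRS junction is
#' annotated as cross-spectrum and never flagged: a low correlation there
#' reflects the change of light spectrum, not a bad band. Callers decide what
#' to remove.
#'
#' @param samples list of `spectral_cube` objects.
#' @param threshold flagging threshold on the correlation (default 0.8).
#' @param patch patch size passed to [band_matrix_set()].
#' @return data.frame with columns `band_i`, `band_j`, `correlation`,
#'   `cross_spectrum`, `flagged`.
#' @export
spectral_correlation_screen <- function(samples, threshold = 0.8,
                                        patch = c(64, 64)) {
  bm <- band_matrix_set(samples, patch)
  b <- ncol(bm$P)
  if (b < 2) stop("config error: need at least 2 bands")
  i <- seq_len(b - 1L)
  rho <- vapply(i, function(k) stats::cor(bm$P[, k], bm$P[, k + 1L]),
                numeric(1))
  cross <- bm$spectrum_tags[i] != bm$spectrum_tags[i + 1L]
  data.frame(band_i = i, band_j = i + 1L, correlation = rho,
             cross_spectrum = cross,
             flagged = !cross & rho < threshold)
}

#' Fit a PCA whitening transform over band variables
#'
#' Eigendecomposes the bands-by-bands covariance (pooled patch pixels as
#' observations) and returns the PCA whitening map
#' \eqn{W = \Lambda^{-1/2} U^\top}. Components with eigenvalue below
#' `epsilon` times the largest eigenvalue are dropped. On the fitting data
#' the whitened variables have identity covariance.
#'
#' @param bands a `band_matrix_set` (or plain observations x variables
#'   matrix).
#' @param epsilon relative variance floor for discarding components.
#' @return object of class `whitening_model` with elements `W`, `mean`,
#'   `eigenvalues`, `eigenvectors`, `epsilon`.
#' @export
fit_whitening <- function(bands, epsilon = 1e-8) {
  X <- if (inherits(bands, "band_matrix_set")) bands$P else as.matrix(bands)
  if (ncol(X) < 2) stop("config error: need at least 2 band variables")
  mu <- colMeans(X)
  C <- stats::cov(X)
  eg <- eigen(C, symmetric = TRUE)
  if (eg$values[1] <= 0)
    stop("degenerate-covariance error: all band variables are constant")
  keep <- eg$values >= epsilon * eg$values[1]
  W <- diag(1 / sqrt(eg$values[keep]), sum(keep)) %*% t(eg$vectors[, keep,
                                                                   drop = FALSE])
  structure(list(W = W, mean = mu, eigenvalues = eg$values,
                 eigenvectors = eg$vectors, epsilon = epsilon,
                 n_retained = sum(keep)),
            class = "whitening_model")
}

#' Apply a fitted whitening transform
#' @param object a `whitening_model`.
#' @param newdata observations x variables matrix (same variables as fitted).
#' @param ... unused.
#' @return observations x retained-components matrix with decorrelated,
#'   unit-variance columns.
#' @export
predict.whitening_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  sweep(X, 2, object$mean) %*% t(object$W)
}

#' @export
print.whitening_model <- function(x, ...) {
  cat(sprintf("whitening_model: %d variables -> %d components (epsilon %g)\n",
              length(x$mean), x$n_retained, x$epsilon))
  invisible(x)
}

#' Choose the initial band pair for linear-prediction selection
#'
#' When both light spectra are present the pair is the middle band of the
#' visual spectrum and the middle band of the infrared spectrum (lower middle
#' for even counts). With a single spectrum the most dissimilar pair is found
#' exhaustively: the unordered pair maximizing the error of linearly
#' predicting one band from the other.
#'
#' @param spectrum_tags length-b character vector of band spectrum tags.
#' @param bands a `band_matrix_set` (required for the single-spectrum
#'   fallback).
#' @return integer vector of two 1-based band indices.
#' @export
choose_initial_pair <- function(spectrum_tags, bands = NULL) {
  b <- length(spectrum_tags)
  if (b < 2) stop("config error: need at least 2 bands")
  lower_middle <- function(idx) idx[(length(idx) + 1L) %/% 2L]
  if (all(c("VS", "IRS") %in% spectrum_tags)) {
    return(c(lower_middle(which(spectrum_tags == "VS")),
             lower_middle(which(spectrum_tags == "IRS"))))
  }
  if (is.null(bands))
    stop("config error: single-spectrum data needs a band_matrix_set")
  best <- c(1L, 2L); best_e <- -Inf
  for (i in 1:(b - 1)) for (j in (i + 1):b) {
    e <- max(lp_fit(bands$P[, i, drop = FALSE], bands$P[, j])$error,
             lp_fit(bands$P[, j, drop = FALSE], bands$P[, i])$error)
    if (e > best_e) { best_e <- e; best <- c(i, j) }
  }
  best
}

#' Linear prediction of one band from selected bands
#'
#' Fits the affine model `y ~ a0 + sum_j aj * Bj` by least squares, where the
#' `Bj` are the columns of `S`. The normal-equations solution
#' \eqn{a = (Y^\top Y)^{-1} Y^\top y} (with `Y = [1 S]`) is computed by a QR
#' factorization rather than an explicit inverse; a rank-deficient `Y` falls
#' back to a ridge solution with jitter 1e-8 and a warning.
#'
#' @param S numeric matrix (pixels x selected bands); must have >= 1 column.
#' @param y numeric vector, the candidate band's pooled pixels.
#' @return list with `a` (intercept first), `pred` and `error`
#'   (Euclidean norm of `pred - y`).
#' @export
lp_fit <- function(S, y) {
  S <- as.matrix(S)
  if (ncol(S) < 1) stop("config error: the selected set must be non-empty")
  Y <- cbind(1, S)
  fit <- stats::lm.fit(Y, y)
  if (fit$rank < ncol(Y)) {
    warning("rank-deficient prediction basis; using ridge jitter 1e-8")
    G <- crossprod(Y) + diag(1e-8, ncol(Y))
    a <- solve(G, crossprod(Y, y))
    pred <- as.numeric(Y %*% a)
  } else {
    a <- fit$coefficients
    pred <- y - fit$residuals
  }
  list(a = as.numeric(a), pred = as.numeric(pred),
       error = sqrt(sum((pred - y)^2)))
}

#' Greedy linear-prediction band selection
#'
#' Starting from the initial band pair, repeatedly adds the band whose pooled
#' centre-patch pixels are worst predicted (largest Euclidean prediction
#' error) as an affine combination of the already-selected bands, until `k`
#' bands are selected. The greedy order is deterministic; ties break to the
#' lowest band index. Selecting `k` bands and then extending the selection
#' yields the same first `k` choices (prefix property).
#'
#' Optional whitening decorrelates the band variables before selection with
#' the PCA whitening map of [fit_whitening()]. It is off by default: a signal
#' whitening fitted on the very data used for selection equalizes all
#' pairwise band correlations, which blunts the dissimilarity criterion the
#' greedy search relies on (see the package vignette).
#'
#' @param samples list of `spectral_cube` objects.
#' @param k number of bands to select (2..b).
#' @param patch centre patch size, default 64 x 64.
#' @param whiten logical; whiten band variables before selection.
#' @param epsilon variance floor used when `whiten = TRUE`.
#' @return object of class `band_selection`: `selected` (ordered indices),
#'   `error_trace` (LP error of each greedy addition, length k - 2),
#'   `initial_pair`, `wavelengths_nm`, `spectrum_tags`, `whitened`.
#' @export
select_bands <- function(samples, k, patch = c(64, 64), whiten = FALSE,
                         epsilon = 1e-8) {
  bm <- band_matrix_set(samples, patch)
  b <- ncol(bm$P)
  if (k < 2 || k > b) stop("config error: k must be in 2..", b)
  P <- bm$P
  if (whiten) {
    wm <- fit_whitening(bm, epsilon)
    # symmetric (ZCA-form) completion of the PCA map keeps the i-th whitened
    # variable attached to band i
    keep <- seq_len(wm$n_retained)
    U <- wm$eigenvectors[, keep, drop = FALSE]
    P <- sweep(P, 2, wm$mean) %*% U %*%
      diag(1 / sqrt(wm$eigenvalues[keep]), length(keep)) %*% t(U)
  }
  sel <- choose_initial_pair(bm$spectrum_tags, bm)
  trace <- numeric(0)
  while (length(sel) < k) {
    cand <- setdiff(seq_len(b), sel)
    errs <- vapply(cand, function(j)
      suppressWarnings(lp_fit(P[, sel, drop = FALSE], P[, j])$error),
      numeric(1))
    pick <- cand[which.max(errs)]  # which.max takes the lowest index on ties
    trace <- c(trace, max(errs))
    sel <- c(sel, pick)
  }
  structure(list(selected = sel, error_trace = trace,
                 initial_pair = sel[1:2],
                 wavelengths_nm = bm$wavelengths_nm,
                 spectrum_tags = bm$spectrum_tags, whitened = whiten),
            class = "band_selection")
}

#' @export
print.band_selection <- function(x, ...) {
  cat(sprintf("band_selection: %d of %d bands (whitened: %s)\n",
              length(x$selected), length(x$wavelengths_nm), x$whitened))
  cat("  initial pair:", x$initial_pair[1], "and", x$initial_pair[2], "\n")
  cat("  order:", paste(x$selected, collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.band_selection <- function(x, ...) {
  steps <- seq_along(x$error_trace) + 2L
  plot(steps, x$error_trace, type = "b", xlab = "bands selected",
       ylab = "LP prediction error of the added band",
       main = "Greedy linear-prediction band selection", ...)
  invisible(x)
}
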