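#' Fit a global PCA feature reducer
#'
#' Mean-centred principal-component projection fitted on training features
#' only; one map shared by all classes.
#'
#' @param features numeric samples x d matrix.
#' @param n_components number of components, at most min(samples - 1, d).
#' @return object of class `ms_reducer` (kind `"global_pca"`) with
#'   explained-variance ratios in `$explained`.
#' @export
fit_global_pca <- function(features, n_components) {
  X <- as.matrix(features)
  if (n_components > min(nrow(X) - 1L, ncol(X)))
    stop("config error: n_components > min(samples - 1, d)")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  structure(list(kind = "global_pca", n_components = as.integer(n_components),
                 maps = list(global = list(center = pc$center,
                                           rotation = pc$rotation)),
                 explained = (pc$sdev^2 / sum(pc$sdev^2))[1:n_components]),
            class = "ms_reducer")
}

#' Feature selection via concave minimization (FSV)
#'
#' Sparse linear separation of two classes by successive linear programs.
#' The misclassification slack of a separating plane `w.x = gamma` is
#' minimized together with `lambda` times a smooth concave surrogate of the
#' zero-norm of `w` (`1 - exp(-alpha |w_j|)`); each outer iteration
#' linearizes the surrogate at the current solution and solves the resulting
#' LP. Selected features are the `n_features` largest-magnitude surviving
#' weights; ties break to the lowest column index.
#'
#' @param features samples x d matrix.
#' @param binary_labels length-n vector with exactly two distinct values;
#'   the first level (sorted order) is taken as the positive class.
#' @param n_features number of features to retain.
#' @param lambda sparsity weight in `[0, 1)`; `lambda = 0` is a plain
#'   linear-separation LP without sparsity pressure.
#' @param alpha concavity parameter of the exponential surrogate.
#' @param max_iter,tol outer-iteration budget and convergence tolerance on
#'   the weight vector.
#' @return object of class `ms_reducer` (kind `"global_fsv"`) with
#'   `$selected` (column indices) and `$weights`.
#' @export
fit_fsv <- function(features, binary_labels, n_features, lambda = 0.05,
                    alpha = 5, max_iter = 50L, tol = 1e-6) {
  X <- as.matrix(features)
  lv <- sort(unique(as.character(binary_labels)))
  if (length(lv) != 2) stop("data error: FSV needs exactly two classes")
  A <- X[binary_labels == lv[1], , drop = FALSE]
  B <- X[binary_labels == lv[2], , drop = FALSE]
  d <- ncol(X); mA <- nrow(A); mB <- nrow(B)
  v <- rep(1, d)
  w <- rep(0, d); gam <- 0
  for (it in seq_len(max_iter)) {
    cv <- if (lambda > 0) lambda * alpha * exp(-alpha * v) else rep(0, d)
    sol <- fsv_lp(A, B, cv)
    if (max(abs(sol$w - w)) < tol && it > 1) { w <- sol$w; gam <- sol$gamma; break }
    w <- sol$w; gam <- sol$gamma
    v <- abs(w)
    if (lambda == 0) break
  }
  ord <- order(-abs(w), seq_len(d))  # magnitude desc, then lowest index
  sel <- sort(ord[seq_len(min(n_features, d))])
  structure(list(kind = "global_fsv", n_features = as.integer(n_features),
                 maps = list(global = list(selected = sel)),
                 weights = w, gamma = gam, selected = sel,
                 lambda = lambda, iterations = it),
            class = "ms_reducer")
}

# two-phase tableau simplex with Bland's rule for
#   min c'x  s.t.  Ax >= b, x >= 0   (b >= 0)
# Dense and unoptimized, which is fine for the small successive FSV programs.
lp_solve_ge <- function(cvec, A, b, max_pivots = 20000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(all(b >= 0))
  # columns: x (n), surplus (m), artificial (m)
  Tb <- cbind(A, -diag(m), diag(m), b)
  basis <- n + m + seq_len(m)
  cost1 <- c(rep(0, n + m), rep(1, m))
  pivot_to <- function(Tb, obj, basis) {
    repeat {
      red <- obj - crossprod(obj[basis], Tb[, seq_along(obj), drop = FALSE])
      ent <- which(red < -1e-9)[1]
      if (is.na(ent)) return(list(Tb = Tb, basis = basis, status = 0L))
      col <- Tb[, ent]
      ok <- which(col > 1e-9)
      if (!length(ok)) return(list(Tb = Tb, basis = basis, status = 1L))
      ratio <- Tb[ok, ncol(Tb)] / col[ok]
      # Bland: among min-ratio rows leave the smallest basis index
      cand <- ok[ratio <= min(ratio) + 1e-12]
      lv <- cand[which.min(basis[cand])]
      Tb[lv, ] <- Tb[lv, ] / Tb[lv, ent]
      upd <- setdiff(seq_len(nrow(Tb)), lv)
      Tb[upd, ] <- Tb[upd, ] - Tb[upd, ent] %o% Tb[lv, ]
      basis[lv] <- ent
    }
  }
  ph1 <- pivot_to(Tb, cost1, basis)
  if (ph1$status != 0L ||
      sum(ph1$Tb[basis_rows <- seq_len(m), ncol(Tb)][ph1$basis > n + m]) > 1e-7)
    stop("solver error: linear program infeasible")
  Tb <- ph1$Tb; basis <- ph1$basis
  Tb <- Tb[, c(seq_len(n + m), ncol(Tb))]  # drop artificial columns
  # drive any artificial still in the basis out (degenerate rows): they have
  # zero value; pivot on any nonzero column, else the row is redundant
  for (r in which(basis > n + m)) {
    piv <- which(abs(Tb[r, seq_len(n + m)]) > 1e-9)[1]
    if (is.na(piv)) { basis[r] <- NA; next }
    Tb[r, ] <- Tb[r, ] / Tb[r, piv]
    upd <- setdiff(seq_len(m), r)
    Tb[upd, ] <- Tb[upd, ] - Tb[upd, piv] %o% Tb[r, ]
    basis[r] <- piv
  }
  live <- !is.na(basis)
  ph2 <- pivot_to(Tb[live, , drop = FALSE], c(cvec, rep(0, m)), basis[live])
  if (ph2$status != 0L) stop("solver error: linear program unbounded")
  x <- numeric(n + m)
  x[ph2$basis] <- ph2$Tb[, ncol(ph2$Tb)]
  x[seq_len(n)]
}

# one FSV linearization step: minimize mean slacks + cv . v over
# (w, gamma, y, z, v) s.t. Aw - gamma + y >= 1, -(Bw - gamma) + z >= 1,
# v >= w >= -v, expressed in non-negative variables.
fsv_lp <- function(A, B, cv) {
  d <- ncol(A); mA <- nrow(A); mB <- nrow(B)
  # x = [p (d), q (d), g+ , g-, y (mA), z (mB), v (d)], w = p - q, gamma = g+ - g-
  nx <- 3 * d + 2 + mA + mB
  obj <- c(rep(0, 2 * d + 2), rep(1 / mA, mA), rep(1 / mB, mB), cv)
  A2 <- matrix(0, mA + mB + 2 * d, nx)
  b2 <- c(rep(1, mA + mB), rep(0, 2 * d))
  # class-A margin rows
  A2[1:mA, 1:d] <- A
  A2[1:mA, (d + 1):(2 * d)] <- -A
  A2[1:mA, 2 * d + 1] <- -1
  A2[1:mA, 2 * d + 2] <- 1
  A2[cbind(1:mA, 2 * d + 2 + 1:mA)] <- 1
  # class-B margin rows
  r <- mA + 1:mB
  A2[r, 1:d] <- -B
  A2[r, (d + 1):(2 * d)] <- B
  A2[r, 2 * d + 1] <- 1
  A2[r, 2 * d + 2] <- -1
  A2[cbind(r, 2 * d + 2 + mA + 1:mB)] <- 1
  # v - w >= 0 and v + w >= 0
  r <- mA + mB + 1:d
  A2[cbind(r, 1:d)] <- -1
  A2[cbind(r, (d + 1):(2 * d))] <- 1
  A2[cbind(r, 2 * d + 2 + mA + mB + 1:d)] <- 1
  r <- mA + mB + d + 1:d
  A2[cbind(r, 1:d)] <- 1
  A2[cbind(r, (d + 1):(2 * d))] <- -1
  A2[cbind(r, 2 * d + 2 + mA + mB + 1:d)] <- 1
  x <- lp_solve_ge(obj, A2, b2)
  list(w = x[1:d] - x[(d + 1):(2 * d)], gamma = x[2 * d + 1] - x[2 * d + 2])
}

#' Fit one reducer per unordered class pair
#'
#' For one-vs-one classification each class pair gets its own map, fitted on
#' that pair's training samples only.
#'
#' @param kind `"pca"` or `"fsv"`.
#' @param features samples x d matrix.
#' @param labels class labels (>= 2 classes, each with >= 2 samples).
#' @param size components (PCA) or features (FSV) per pair map.
#' @param ... passed to [fit_global_pca()] or [fit_fsv()].
#' @return object of class `ms_reducer` (kind `"pairwise_pca"` or
#'   `"pairwise_fsv"`) holding `choose(n_classes, 2)` maps keyed
#'   `"A|B"` with A < B.
#' @export
fit_pairwise <- function(kind = c("pca", "fsv"), features, labels, size, ...) {
  kind <- match.arg(kind)
  X <- as.matrix(features)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) < 2) stop("data error: need >= 2 classes")
  small <- cls[table(factor(labels, cls)) < 2]
  if (length(small))
    stop("data error: class(es) with < 2 samples: ",
         paste(small, collapse = ", "))
  maps <- list()
  for (i in 1:(length(cls) - 1)) for (j in (i + 1):length(cls)) {
    key <- paste(cls[i], cls[j], sep = "|")
    idx <- labels %in% c(cls[i], cls[j])
    sub <- if (kind == "pca")
      fit_global_pca(X[idx, , drop = FALSE],
                     min(size, sum(idx) - 1L, ncol(X)))
    else
      fit_fsv(X[idx, , drop = FALSE], labels[idx], size, ...)
    maps[[key]] <- sub$maps$global
  }
  structure(list(kind = paste0("pairwise_", kind), size = as.integer(size),
                 maps = maps, classes = cls),
            class = "ms_reducer")
}

#' Apply a fitted reducer
#'
#' @param object an `ms_reducer`.
#' @param newdata samples x d matrix with the training dimensionality.
#' @param pair for pairwise reducers, the class pair key `"A|B"` (or a
#'   length-2 character vector) naming the map to apply.
#' @param ... unused.
#' @return transformed samples x (components or selected-features) matrix.
#' @export
predict.ms_reducer <- function(object, newdata, pair = NULL, ...) {
  X <- as.matrix(newdata)
  map <- if (startsWith(object$kind, "pairwise_")) {
    if (is.null(pair)) stop("contract error: pairwise reducer needs a pair")
    if (length(pair) == 2) pair <- paste(sort(pair), collapse = "|")
    object$maps[[pair]] %||%
      stop("contract error: no map for pair ", pair)
  } else object$maps$global
  if (!is.null(map$rotation)) {
    sweep(X, 2, map$center) %*% map$rotation
  } else {
    X[, map$selected, drop = FALSE]
  }
}

#' @export
print.ms_reducer <- function(x, ...) {
  cat(sprintf("ms_reducer: %s, %d map(s)\n", x$kind, length(x$maps)))
  invisible(x)
}
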