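make_band_cubes <- function(P, wl = NULL, tags = NULL, H = 8, W = 8) {
  # one cube per column-block: P is (H*W) x b for a single sample
  b <- ncol(P)
  tags <- tags %||% rep("VS", b)
  if (is.null(wl)) {
    wl <- numeric(b)
    wl[tags == "VS"] <- seq(470, by = 20, length.out = sum(tags == "VS"))
    wl[tags == "IRS"] <- seq(1150, by = 20, length.out = sum(tags == "IRS"))
  }
  list(spectral_cube(array(P, c(H, W, b)), wl, tags, "s1"))
}

test_that("adjacent-band correlation screen flags noise, exempts the junction", {
  set.seed(31)
  base <- runif(64, 1, 2)
  # bands: two near-duplicates, an independent-noise band, then IRS pair
  P <- cbind(base, base + rnorm(64, 0, 1e-3), runif(64),
             base * 2, base * 2 + rnorm(64, 0, 1e-3))
  cubes <- make_band_cubes(pmax(P, 0), tags = c("VS", "VS", "VS", "IRS", "IRS"))
  scr <- spectral_correlation_screen(cubes, threshold = 0.8, patch = c(8, 8))
  expect_gt(scr$correlation[1], 0.99)
  expect_false(scr$flagged[1])
  expect_lt(abs(scr$correlation[2]), 0.5)
  expect_true(scr$flagged[2])
  # junction pair (band 3 -> 4) is cross-spectrum, never flagged
  expect_true(scr$cross_spectrum[3])
  expect_false(scr$flagged[3])
})

test_that("PCA whitening reproduces the eigendecomposition and decorrelates", {
  set.seed(32)
  X <- matrix(rnorm(600), 120, 5) %*% matrix(rnorm(25), 5) + 3
  wm <- fit_whitening(X)
  Z <- predict(wm, X)
  expect_lt(max(abs(stats::cov(Z) - diag(ncol(Z)))), 1e-6)
  # W equals lambda^(-1/2) U^T from an independent eigendecomposition
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  W_oracle <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  # eigenvectors are sign-ambiguous; compare row by row up to sign
  for (r in seq_len(nrow(wm$W)))
    expect_equal(abs(wm$W[r, ]), abs(W_oracle[r, ]), tolerance = 1e-8)
  # two perfectly correlated bands leave a single retained component
  Y <- cbind(X[, 1], 2 * X[, 1])
  expect_equal(fit_whitening(Y)$n_retained, 1L)
  expect_error(fit_whitening(matrix(1, 10, 3)), "degenerate-covariance")
})

test_that("whitening already-whitened data is an orthonormal map", {
  set.seed(33)
  X <- matrix(rnorm(400), 100, 4) %*% matrix(rnorm(16), 4)
  Z <- predict(fit_whitening(X), X)
  wm2 <- fit_whitening(Z)
  M <- wm2$W %*% t(wm2$W)  # identity if the second map is orthonormal
  expect_equal(M, diag(nrow(M)), tolerance = 1e-6)
})

test_that("initial pair: middle of each spectrum, or the most dissimilar pair", {
  tags <- rep(c("VS", "IRS"), c(13, 26))
  expect_equal(choose_initial_pair(tags), c(7L, 26L))
  expect_equal(choose_initial_pair(rep(c("VS", "IRS"), c(4, 6))), c(2L, 7L))
  # single spectrum, band 3 duplicates band 1: the duplicate pair loses
  set.seed(34)
  b1 <- runif(64); b2 <- runif(64)
  cubes <- make_band_cubes(cbind(b1, b2, b1))
  bm <- band_matrix_set(cubes, patch = c(8, 8))
  pr <- choose_initial_pair(rep("VS", 3), bm)
  expect_true(2L %in% pr)
  expect_error(choose_initial_pair("VS"), "config error")
  # exactly two bands: that pair
  cubes2 <- make_band_cubes(cbind(b1, b2))
  expect_equal(choose_initial_pair(rep("VS", 2), band_matrix_set(cubes2, c(8, 8))),
               c(1L, 2L))
})

test_that("lp_fit solves the affine normal equations", {
  set.seed(35)
  S <- matrix(runif(20), 10, 2)
  y <- 2 + 3 * S[, 1] - S[, 2]
  f <- lp_fit(S, y)
  expect_equal(f$a, c(2, 3, -1), tolerance = 1e-8)
  expect_lt(f$error, 1e-10)
  # normal-equations oracle on a 10-pixel toy with noise
  y2 <- y + rnorm(10, 0, 0.3)
  f2 <- lp_fit(S, y2)
  Y <- cbind(1, S)
  a_oracle <- solve(t(Y) %*% Y, t(Y) %*% y2)
  expect_equal(f2$a, as.numeric(a_oracle), tolerance = 1e-8)
  expect_equal(f2$error, sqrt(sum((Y %*% a_oracle - y2)^2)), tolerance = 1e-8)
  expect_error(lp_fit(matrix(nrow = 10, ncol = 0), y), "non-empty")
  expect_warning(lp_fit(cbind(S[, 1], S[, 1]), y), "rank-deficient")
})

test_that("greedy selection prefers unpredictable bands and is a prefix chain", {
  rc <- generate_band_redundancy_case(4, 2, seed = 36, n_samples = 2,
                                      noise_sd = 0.01)
  sel6 <- select_bands(rc$cubes, k = 6, patch = c(16, 16))
  expect_equal(sort(sel6$selected[1:4]), 1:4)  # independent bands first
  expect_length(sel6$error_trace, 4)
  sel4 <- select_bands(rc$cubes, k = 4, patch = c(16, 16))
  expect_equal(sel4$selected, sel6$selected[1:4])  # prefix property
  expect_error(select_bands(rc$cubes, k = 7, patch = c(16, 16)),
               "config error")

  # an exact duplicate band is selected last among distinguishable bands
  set.seed(37)
  P <- matrix(runif(64 * 3), 64, 3)
  cubes <- make_band_cubes(cbind(P, P[, 1]),
                           tags = c("VS", "VS", "IRS", "IRS"),
                           wl = c(470, 490, 1150, 1170))
  sel <- suppressWarnings(select_bands(cubes, k = 4, patch = c(8, 8)))
  expect_equal(sel$selected[4], 4L)
  expect_lt(sel$error_trace[2], 1e-8)
})

test_that("selection works for every k on a two-spectrum cube", {
  set.seed(38)
  cubes <- lapply(1:2, function(i)
    make_cube(16, 16, b = 8, seed = 40 + i,
              tags = rep(c("VS", "IRS"), each = 4)))
  full <- select_bands(cubes, k = 8, patch = c(16, 16))
  expect_setequal(full$selected, 1:8)
  for (k in c(3, 5, 7))
    expect_equal(select_bands(cubes, k = k, patch = c(16, 16))$selected,
                 full$selected[1:k])
  # whitened variant stays a valid selection
  w <- select_bands(cubes, k = 4, patch = c(16, 16), whiten = TRUE)
  expect_length(unique(w$selected), 4)
})
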