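#' Perception-like (Tamura) features
#'
#' Per band, five statistics modelled on human texture perception, in the
#' order coarseness, directionality, line-likeness, roughness, contrast:
#'
#' * coarseness: best-window size statistic from the classic averaging
#'   pyramid with windows 2^1 .. 2^`tamura_kmax` pixels;
#' * directionality: sharpness of the gradient-orientation histogram
#'   (1 = a single dominant orientation, 0 = isotropic);
#' * line-likeness: average direction co-occurrence along the local edge
#'   direction at distance 4 pixels;
#' * roughness: coarseness + contrast;
#' * contrast: sigma / kurtosis^(1/4) on the intensity distribution
#'   (0 for a constant band).
#'
#' @param cube a `spectral_cube`.
#' @param cfg a [descriptor_config()]; `tamura_kmax` sets the pyramid depth.
#' @return `feature_vector` with `band_block_size` 5.
#' @export
perception_features <- function(cube, cfg = descriptor_config()) {
  d <- dim(cube$pixels)
  if (min(d[1], d[2]) < 2^cfg$tamura_kmax)
    stop("config error: band ", d[1], "x", d[2],
         " too small for coarseness pyramid 2^", cfg$tamura_kmax)
  vals <- vapply(seq_len(d[3]), function(k) {
    band <- cube$pixels[, , k]
    crs <- tamura_coarseness(band, cfg$tamura_kmax)
    ctr <- tamura_contrast(band)
    dir <- tamura_directionality(band)
    lin <- tamura_linelikeness(band)
    c(crs, dir, lin, crs + ctr, ctr)
  }, numeric(5))
  feature_vector("perception", as.numeric(vals), 5L, d[3])
}

# mean over s x s windows anchored at top-left; (H-s+1) x (W-s+1)
box_mean <- function(img, s) {
  H <- nrow(img); W <- ncol(img)
  S <- matrix(0, H + 1, W + 1)
  S[-1, -1] <- apply(apply(img, 2, cumsum), 1, cumsum) |> t()
  (S[(s + 1):(H + 1), (s + 1):(W + 1)] - S[1:(H - s + 1), (s + 1):(W + 1)] -
     S[(s + 1):(H + 1), 1:(W - s + 1)] + S[1:(H - s + 1), 1:(W - s + 1)]) / s^2
}

tamura_coarseness <- function(band, kmax) {
  H <- nrow(band); W <- ncol(band)
  ks <- 1:kmax
  ks <- ks[2^(ks + 1) <= min(H, W)]  # need two adjacent windows
  if (!length(ks)) return(1)
  # common valid region across scales
  smax <- 2^max(ks)
  vh <- H - 2 * smax + 1; vw <- W - 2 * smax + 1
  Ebest <- matrix(-Inf, vh, vw)
  Sbest <- matrix(1, vh, vw)
  for (k in ks) {
    s <- 2^k
    A <- box_mean(band, s)
    Eh <- abs(A[, (s + 1):ncol(A), drop = FALSE] -
                A[, 1:(ncol(A) - s), drop = FALSE])[1:vh, 1:vw, drop = FALSE]
    Ev <- abs(A[(s + 1):nrow(A), , drop = FALSE] -
                A[1:(nrow(A) - s), , drop = FALSE])[1:vh, 1:vw, drop = FALSE]
    E <- pmax(Eh, Ev)
    upd <- E > Ebest
    Ebest[upd] <- E[upd]
    Sbest[upd] <- s
  }
  mean(Sbest)
}

tamura_contrast <- function(band) {
  x <- as.numeric(band)
  v <- mean((x - mean(x))^2)
  if (v <= 0) return(0)
  kurt <- mean((x - mean(x))^4) / v^2
  sqrt(v) / kurt^0.25
}

# central-difference gradients; orientation folded to [0, pi)
tamura_gradients <- function(band) {
  H <- nrow(band); W <- ncol(band)
  dh <- band[2:(H - 1), 3:W] - band[2:(H - 1), 1:(W - 2)]
  dv <- band[3:H, 2:(W - 1)] - band[1:(H - 2), 2:(W - 1)]
  theta <- atan2(dv, dh) %% pi
  list(theta = theta, mag = sqrt(dh^2 + dv^2))
}

# orientation histogram over n bins of [0, pi); exposed for testing the
# stripe-rotation behaviour
tamura_orientation_hist <- function(band, nbins = 16L) {
  g <- tamura_gradients(band)
  thr <- 0.01 * max(g$mag)
  if (max(g$mag) <= 0) return(rep(0, nbins))
  keep <- g$mag >= thr
  bins <- pmin(floor(g$theta[keep] / pi * nbins) + 1L, nbins)
  tabulate(bins, nbins)
}

tamura_directionality <- function(band, nbins = 16L) {
  h <- tamura_orientation_hist(band, nbins)
  tot <- sum(h)
  if (tot == 0) return(0)
  p <- h / tot
  m <- which.max(p)
  i <- seq_len(nbins)
  dbin <- pmin(abs(i - m), nbins - abs(i - m))
  phi2 <- (dbin * pi / nbins)^2
  unif <- mean((pmin(i - 1, nbins - (i - 1)) * pi / nbins)^2)
  max(0, 1 - sum(p * phi2) / unif)
}

tamura_linelikeness <- function(band, nbins = 16L, dist = 4L) {
  g <- tamura_gradients(band)
  if (max(g$mag) <= 0) return(0)
  thr <- 0.01 * max(g$mag)
  H <- nrow(g$theta); W <- ncol(g$theta)
  keep <- which(g$mag >= thr, arr.ind = TRUE)
  if (!nrow(keep)) return(0)
  th <- g$theta[keep]
  b1 <- pmin(floor(th / pi * nbins) + 1L, nbins)
  nr <- keep[, 1] + round(dist * sin(th))
  nc <- keep[, 2] + round(dist * cos(th))
  ok <- nr >= 1 & nr <= H & nc >= 1 & nc <= W
  if (!any(ok)) return(0)
  idx <- cbind(nr[ok], nc[ok])
  ok2 <- g$mag[idx] >= thr
  if (!any(ok2)) return(0)
  b2 <- pmin(floor(g$theta[idx[ok2, , drop = FALSE]] / pi * nbins) + 1L, nbins)
  b1 <- b1[ok][ok2]
  sum(cos((b1 - b2) * 2 * pi / nbins)) / length(b1)
}
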