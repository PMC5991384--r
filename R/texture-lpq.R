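#' Rotation-invariant local phase quantization
#'
#' Per band: for every pixel, a characteristic local orientation is estimated
#' from the signs of the imaginary parts of short-time Fourier coefficients
#' taken at the lowest non-zero frequency along `lpq_angles` directions
#' (the argument of the sign-weighted resultant vector), and quantized back
#' to the same directional grid. The LPQ code is then read in the rotated
#' local frame: the four lowest non-zero frequencies (along the
#' characteristic orientation, its perpendicular, and the two diagonals) are
#' evaluated with a uniform `lpq_window` x `lpq_window` short-time Fourier
#' window and the signs of their real and imaginary parts are packed into an
#' 8-bit code, giving a 256-bin histogram per band.
#'
#' @param cube a `spectral_cube`.
#' @param cfg a [descriptor_config()]; `lpq_angles` must be divisible by 4.
#' @return `feature_vector` with `band_block_size` 256; bins hold raw pixel
#'   counts over all pixels with a full window.
#' @export
lpq_features <- function(cube, cfg = descriptor_config()) {
  d <- dim(cube$pixels)
  w <- cfg$lpq_window; M <- cfg$lpq_angles
  if (d[1] < w || d[2] < w)
    stop("config error: band smaller than the LPQ window")
  if (M %% 4 != 0) stop("config error: lpq_angles must be divisible by 4")
  bank <- lpq_filter_bank(d[1], d[2], w, M)
  vals <- vapply(seq_len(d[3]), function(k) {
    tabulate(lpq_codes(cube$pixels[, , k], bank) + 1L, nbins = 256L)
  }, numeric(256))
  feature_vector("lpq", as.numeric(vals), 256L, d[3])
}

# FFTs of the directional STFT kernels for one image geometry, cached.
# Two full-circle banks at the lowest non-zero frequency a = 1/w:
# the main bank at angles 2*pi*i/M (also used for orientation estimation)
# and a pi/4-offset bank supplying the diagonal frequencies.
lpq_filter_bank <- function(H, W, w, M) {
  key <- sprintf("lpq_%d_%d_%d_%d", H, W, w, M)
  if (!is.null(.ms_cache[[key]])) return(.ms_cache[[key]])
  m <- (w - 1L) %/% 2L
  P1 <- H + w - 1L; P2 <- W + w - 1L
  a <- 1 / w
  offs <- -m:m
  kernel_fft <- function(theta) {
    u <- a * c(cos(theta), sin(theta))  # (row, col) frequency
    ph <- 2 * pi * (outer(offs * u[1], offs * u[2], `+`))
    k <- matrix(complex(real = cos(ph), imaginary = sin(ph)), w, w)
    pad <- matrix(0 + 0i, P1, P2)
    pad[1:w, 1:w] <- k
    stats::fft(pad)
  }
  th <- 2 * pi * (0:(M - 1)) / M
  bank <- list(main = lapply(th, kernel_fft),
               diag = lapply(th + pi / 4, kernel_fft),
               H = H, W = W, w = w, M = M, m = m, P1 = P1, P2 = P2)
  .ms_cache[[key]] <- bank
  bank
}

lpq_codes <- function(band, bank) {
  w <- bank$w; m <- bank$m; M <- bank$M
  H <- bank$H; W <- bank$W
  pad <- matrix(0, bank$P1, bank$P2)
  pad[1:H, 1:W] <- band
  FI <- stats::fft(pad)
  vr <- w:H; vc <- w:W  # full-conv indices of the fully-overlapped centres
  resp <- function(KF) {
    C <- stats::fft(FI * KF, inverse = TRUE) / length(KF)
    C[vr, vc, drop = FALSE]
  }
  Rm <- lapply(bank$main, resp)
  Rd <- lapply(bank$diag, resp)
  # characteristic orientation: argument of the directional resultant
  # weighted by the imaginary STFT parts. Weighting by the value rather than
  # its sign keeps the estimate continuous, so quantizing to the angle grid
  # has no systematic ties and the estimate rotates consistently with the
  # image.
  th <- 2 * pi * (0:(M - 1)) / M
  sr <- 0; si <- 0
  for (i in seq_len(M)) {
    b <- Im(Rm[[i]])
    sr <- sr + b * cos(th[i]); si <- si + b * sin(th[i])
  }
  xi <- atan2(si, sr)
  q <- matrix(as.integer(round(xi / (2 * pi / M))) %% M,
              nrow(xi), ncol(xi))  # 0-based angle index
  # 8-bit codes for each candidate orientation, then pick per pixel
  quarter <- M %/% 4L
  vh <- length(vr); vw <- length(vc)
  codes <- array(0L, c(vh, vw, M))
  for (i in seq_len(M)) {
    f1 <- Rm[[i]]
    f2 <- Rm[[(i - 1L + quarter) %% M + 1L]]
    f3 <- Rd[[i]]
    f4 <- Rd[[(i - 1L - quarter) %% M + 1L]]
    codes[, , i] <-
      (Re(f1) >= 0) + 2L * (Im(f1) >= 0) +
      4L * (Re(f2) >= 0) + 8L * (Im(f2) >= 0) +
      16L * (Re(f3) >= 0) + 32L * (Im(f3) >= 0) +
      64L * (Re(f4) >= 0) + 128L * (Im(f4) >= 0)
  }
  sel <- cbind(as.vector(row(q)), as.vector(col(q)), as.vector(q) + 1L)
  as.integer(codes[sel])
}
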