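#' First-order intensity statistics
#'
#' Per band: mean, variance, skewness, kurtosis (the non-excess fourth
#' standardized moment) and the raw central moments of orders 5 to 11 --
#' 11 features per band. Moments are population moments (divide by the pixel
#' count). Skewness and kurtosis of a zero-variance band are 0 by convention.
#'
#' @param cube a `spectral_cube`.
#' @return `feature_vector` with `band_block_size` 11.
#' @export
histogram_features <- function(cube) {
  b <- n_bands(cube)
  vals <- vapply(seq_len(b), function(k) {
    x <- as.numeric(cube$pixels[, , k])
    m <- mean(x)
    cm <- vapply(2:11, function(p) mean((x - m)^p), numeric(1))
    v <- cm[1]
    if (v > 0) {
      skew <- cm[2] / v^1.5
      kurt <- cm[3] / v^2
    } else {
      skew <- 0; kurt <- 0
    }
    c(m, v, skew, kurt, cm[4:10])
  }, numeric(11))
  feature_vector("histogram", as.numeric(vals), 11L, b)
}
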