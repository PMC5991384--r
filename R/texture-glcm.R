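#' Haralick co-occurrence features
#'
#' Per band: the band is quantized to `cfg$glcm_levels` grey levels by linear
#' min-max scaling, symmetric grey-level co-occurrence matrices are tabulated
#' at every (displacement, angle) combination, the four angle matrices of
#' each displacement are averaged into one rotation-tolerant matrix and
#' normalized to a joint probability, and four Haralick statistics (energy,
#' contrast, homogeneity, correlation) are read off. With 5 displacements
#' this gives 20 features per band.
#'
#' A zero-variance (constant) band has, by convention, contrast 0,
#' homogeneity 1, energy 1 and correlation 1.
#'
#' @param cube a `spectral_cube`.
#' @param cfg a [descriptor_config()].
#' @return `feature_vector` with `band_block_size` =
#'   4 * length(glcm_displacements).
#' @export
glcm_features <- function(cube, cfg = descriptor_config()) {
  d <- dim(cube$pixels)
  if (max(cfg$glcm_displacements) >= min(d[1], d[2]))
    stop("config error: GLCM displacement >= image size")
  block <- 4L * length(cfg$glcm_displacements)
  vals <- vapply(seq_len(d[3]), function(k) {
    glcm_band(cube$pixels[, , k], cfg)
  }, numeric(block))
  feature_vector("glcm", as.numeric(vals), block, d[3])
}

quantize_band <- function(band, levels) {
  rng <- range(band)
  if (rng[1] == rng[2]) return(matrix(1L, nrow(band), ncol(band)))
  q <- floor((band - rng[1]) / (rng[2] - rng[1]) * levels) + 1L
  q[q > levels] <- levels
  q
}

glcm_band <- function(band, cfg) {
  g <- quantize_band(band, cfg$glcm_levels)
  L <- cfg$glcm_levels
  out <- numeric(0)
  for (dd in cfg$glcm_displacements) {
    acc <- matrix(0, L, L)
    for (ang in cfg$glcm_angles_deg) {
      acc <- acc + glcm_counts(g, dd, ang, L)
    }
    P <- acc / sum(acc)  # average of angle GLCMs, normalized to probabilities
    out <- c(out, haralick_stats(P))
  }
  out
}

# symmetric co-occurrence counts at one displacement/angle;
# image-coordinate offsets (drow, dcol): 0 deg -> (0,d), 45 -> (-d,d),
# 90 -> (-d,0), 135 -> (-d,-d)
glcm_counts <- function(g, d, angle_deg, L) {
  off <- switch(as.character(angle_deg),
                "0"   = c(0L, d), "45" = c(-d, d),
                "90"  = c(-d, 0L), "135" = c(-d, -d),
                stop("config error: unsupported GLCM angle ", angle_deg))
  H <- nrow(g); W <- ncol(g)
  r1 <- max(1L, 1L - off[1]):min(H, H - off[1])
  c1 <- max(1L, 1L - off[2]):min(W, W - off[2])
  a <- g[r1, c1, drop = FALSE]
  b <- g[r1 + off[1], c1 + off[2], drop = FALSE]
  cnt <- tabulate((a - 1L) * L + b, nbins = L * L)
  M <- matrix(cnt, L, L, byrow = TRUE)
  M + t(M)  # symmetric pairs
}

haralick_stats <- function(P) {
  L <- nrow(P)
  i <- row(P); j <- col(P)
  energy <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  homogeneity <- sum(P / (1 + abs(i - j)))
  mi <- sum(i * P); mj <- sum(j * P)
  vi <- sum((i - mi)^2 * P); vj <- sum((j - mj)^2 * P)
  correlation <- if (vi <= 0 || vj <= 0) 1
  else sum((i - mi) * (j - mj) * P) / sqrt(vi * vj)
  c(energy, contrast, homogeneity, correlation)
}
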