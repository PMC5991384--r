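#' Binarized statistical image features
#'
#' Per band: the band is correlated with each of `bsif_filter_count`
#' statistically independent linear filters, each response is thresholded at
#' zero (response > 0 gives bit 1), the bits are packed into a code, and the
#' codes are histogrammed over all pixels with a full filter support --
#' 2^10 = 1024 bins per band for the default 10-filter bank.
#'
#' The built-in 7x7x10 bank is learned once, deterministically, by PCA
#' whitening followed by fixed-point ICA on patches sampled from synthetic
#' smooth (1/f spectrum) noise images; an external bank of the same shape can
#' be supplied via `cfg$bsif_filter_bank`.
#'
#' @param cube a `spectral_cube`.
#' @param cfg a [descriptor_config()].
#' @return `feature_vector` with `band_block_size` 2^bsif_filter_count.
#' @export
bsif_features <- function(cube, cfg = descriptor_config()) {
  bank <- cfg$bsif_filter_bank %||%
    bsif_default_bank(cfg$bsif_filter_size, cfg$bsif_filter_count)
  db <- dim(bank)
  if (length(db) != 3L || db[1] != cfg$bsif_filter_size ||
      db[2] != cfg$bsif_filter_size || db[3] != cfg$bsif_filter_count)
    stop("config error: filter bank must be ", cfg$bsif_filter_size, "x",
         cfg$bsif_filter_size, "x", cfg$bsif_filter_count)
  d <- dim(cube$pixels)
  if (d[1] < db[1] || d[2] < db[2])
    stop("config error: band smaller than the BSIF filter")
  nb <- 2L^db[3]
  vals <- vapply(seq_len(d[3]), function(k) {
    tabulate(bsif_codes(cube$pixels[, , k], bank) + 1L, nbins = nb)
  }, numeric(nb))
  feature_vector("bsif", as.numeric(vals), nb, d[3])
}

# codes over the valid (full-support) region; filters applied as correlation
bsif_codes <- function(band, bank) {
  s <- dim(bank)[1]; nf <- dim(bank)[3]
  H <- nrow(band); W <- ncol(band)
  vh <- H - s + 1L; vw <- W - s + 1L
  code <- matrix(0, vh, vw)
  for (f in seq_len(nf)) {
    resp <- matrix(0, vh, vw)
    for (i in seq_len(s)) for (j in seq_len(s)) {
      resp <- resp + bank[i, j, f] *
        band[i:(i + vh - 1L), j:(j + vw - 1L), drop = FALSE]
    }
    # "> 0" with a relative guard so that mathematically-zero responses
    # (zero-mean filter on a flat region) never flip bits through rounding
    thr <- 1e-9 * max(abs(band)) * sum(abs(bank[, , f]))
    code <- code + 2^(f - 1) * (resp > thr)
  }
  as.integer(code)
}

#' The built-in ICA-learned BSIF filter bank
#'
#' Learned once per (size, count) and cached: synthetic 1/f-spectrum noise
#' images are generated from a fixed internal seed, patches are sampled,
#' patch means are removed, the patch cloud is PCA-whitened to `count`
#' dimensions and rotated to statistical independence by symmetric
#' fixed-point ICA (tanh nonlinearity). Rows of the resulting unmixing map
#' are the filters.
#'
#' @param size filter side length in pixels (odd).
#' @param count number of filters (code bits).
#' @return numeric `size` x `size` x `count` array; every filter has zero
#'   mean.
#' @export
bsif_default_bank <- function(size = 7L, count = 10L) {
  key <- sprintf("bsif_%d_%d", size, count)
  if (!is.null(.ms_cache[[key]])) return(.ms_cache[[key]])
  bank <- with_local_seed(20180606L, learn_ica_bank(size, count))
  .ms_cache[[key]] <- bank
  bank
}

# run expr under a temporary RNG state so library calls never disturb the
# caller's random stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

learn_ica_bank <- function(size, count, n_images = 12L, img_side = 96L,
                           n_patches = 6000L) {
  # smooth "natural" images: white noise shaped to a 1/f amplitude spectrum
  imgs <- lapply(seq_len(n_images), function(i) smooth_noise_image(img_side))
  patches <- matrix(0, size * size, n_patches)
  for (p in seq_len(n_patches)) {
    im <- imgs[[sample.int(n_images, 1)]]
    r <- sample.int(img_side - size + 1L, 1)
    cc <- sample.int(img_side - size + 1L, 1)
    patches[, p] <- as.numeric(im[r:(r + size - 1L), cc:(cc + size - 1L)])
  }
  patches <- sweep(patches, 2, colMeans(patches))  # remove patch DC
  C <- patches %*% t(patches) / n_patches
  eg <- eigen(C, symmetric = TRUE)
  V <- diag(1 / sqrt(eg$values[1:count])) %*% t(eg$vectors[, 1:count])
  Z <- V %*% patches  # count x n whitened
  W <- sym_decorrelate(matrix(stats::rnorm(count * count), count))
  for (it in 1:200) {
    G <- tanh(W %*% Z)
    Wn <- G %*% t(Z) / n_patches - diag(rowMeans(1 - G^2)) %*% W
    Wn <- sym_decorrelate(Wn)
    delta <- 1 - min(abs(diag(Wn %*% t(W))))
    W <- Wn
    if (delta < 1e-10) break
  }
  U <- W %*% V  # count x size^2 unmixing filters
  array(t(U), c(size, size, count))
}

smooth_noise_image <- function(side) {
  z <- matrix(stats::rnorm(side^2), side)
  f <- stats::fft(z)
  fr <- c(0:(side %/% 2), -((side - (side %/% 2 + 1)):1)) / side
  rad <- sqrt(outer(fr^2, fr^2, `+`))
  rad[1, 1] <- Inf  # kill DC
  img <- Re(stats::fft(f / rad, inverse = TRUE)) / side^2
  (img - mean(img)) / stats::sd(img)
}

sym_decorrelate <- function(W) {
  s <- eigen(W %*% t(W), symmetric = TRUE)
  s$vectors %*% diag(1 / sqrt(s$values)) %*% t(s$vectors) %*% W
}
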