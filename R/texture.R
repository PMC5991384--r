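#' Texture descriptor configuration
#'
#' Collects the tunable parameters of the six per-band texture descriptors.
#' Defaults follow the configuration used throughout this package: GLCM at
#' displacements 1..5 and angles 0/45/90/135 with 32 quantization levels;
#' rotation-invariant LBP in the (16, 2) configuration; rotation-invariant
#' LPQ with a 15-pixel window over 36 candidate orientations; BSIF with 10
#' learned 7x7 filters; a Tamura coarseness pyramid up to 2^5 windows.
#'
#' @param glcm_displacements integer displacements for pixel pairs.
#' @param glcm_angles_deg co-occurrence angles in degrees.
#' @param glcm_levels grey-level quantization levels (per-band min-max).
#' @param lbp_neighbors,lbp_radius circular LBP sampling geometry.
#' @param lpq_window LPQ short-time Fourier window size (odd).
#' @param lpq_angles number of quantized characteristic orientations.
#' @param bsif_filter_size,bsif_filter_count BSIF filter geometry.
#' @param bsif_filter_bank optional 7x7x10 array overriding the built-in
#'   ICA-learned bank.
#' @param tamura_kmax largest coarseness window is 2^tamura_kmax pixels.
#' @return a list of class `descriptor_config`.
#' @export
descriptor_config <- function(glcm_displacements = 1:5,
                              glcm_angles_deg = c(0, 45, 90, 135),
                              glcm_levels = 32L,
                              lbp_neighbors = 16L, lbp_radius = 2,
                              lpq_window = 15L, lpq_angles = 36L,
                              bsif_filter_size = 7L, bsif_filter_count = 10L,
                              bsif_filter_bank = NULL,
                              tamura_kmax = 5L) {
  stopifnot(lpq_window %% 2 == 1, bsif_filter_size %% 2 == 1,
            lbp_neighbors >= 4, glcm_levels >= 2)
  structure(list(glcm_displacements = as.integer(glcm_displacements),
                 glcm_angles_deg = glcm_angles_deg,
                 glcm_levels = as.integer(glcm_levels),
                 lbp_neighbors = as.integer(lbp_neighbors),
                 lbp_radius = lbp_radius,
                 lpq_window = as.integer(lpq_window),
                 lpq_angles = as.integer(lpq_angles),
                 bsif_filter_size = as.integer(bsif_filter_size),
                 bsif_filter_count = as.integer(bsif_filter_count),
                 bsif_filter_bank = bsif_filter_bank,
                 tamura_kmax = as.integer(tamura_kmax)),
            class = "descriptor_config")
}

#' Construct a feature vector with its per-band block layout
#'
#' @param descriptor descriptor name.
#' @param values numeric vector, band blocks concatenated in band order.
#' @param band_block_size features per band.
#' @param n_bands number of bands represented.
#' @return object of class `feature_vector`.
#' @export
feature_vector <- function(descriptor, values, band_block_size, n_bands) {
  if (length(values) != band_block_size * n_bands)
    stop("feature contract violated: length ", length(values), " != ",
         band_block_size, " x ", n_bands)
  if (anyNA(values) || !all(is.finite(values)))
    stop("feature contract violated: non-finite values in ", descriptor)
  structure(list(descriptor = descriptor, values = as.numeric(values),
                 band_block_size = as.integer(band_block_size),
                 n_bands = as.integer(n_bands)),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("feature_vector '%s': %d values (%d per band x %d bands)\n",
              x$descriptor, length(x$values), x$band_block_size, x$n_bands))
  invisible(x)
}

#' @export
length.feature_vector <- function(x) length(x$values)

#' The per-band block of a feature vector
#' @param fv a `feature_vector`.
#' @param band band position within the vector (1-based).
#' @return numeric vector of length `fv$band_block_size`.
#' @export
band_block <- function(fv, band) {
  i <- (band - 1L) * fv$band_block_size
  fv$values[(i + 1L):(i + fv$band_block_size)]
}

#' Names of the six texture descriptors
#' @return character vector in the package's canonical order.
#' @export
descriptor_names <- function()
  c("glcm", "histogram", "perception", "lbp", "lpq", "bsif")

#' Run texture descriptors on a cube
#'
#' Computes the requested per-band texture descriptors on the cube restricted
#' to `band_subset`. Every descriptor returns one block of features per
#' selected band, concatenated in band order, so vector lengths scale
#' linearly with the number of bands (20, 11, 5, 4116, 256 and 1024 features
#' per band for GLCM, histogram, perception, LBP, LPQ and BSIF).
#'
#' @param cube a `spectral_cube`.
#' @param cfg a [descriptor_config()].
#' @param band_subset optional integer band indices (default: all bands).
#' @param descriptors which descriptors to run (default: all six).
#' @return named list of `feature_vector` objects.
#' @export
extract_all <- function(cube, cfg = descriptor_config(), band_subset = NULL,
                        descriptors = descriptor_names()) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (!is.null(band_subset)) cube <- subset_bands(cube, band_subset)
  bad <- setdiff(descriptors, descriptor_names())
  if (length(bad)) stop("unknown descriptor(s): ", paste(bad, collapse = ", "))
  fns <- list(glcm = function() glcm_features(cube, cfg),
              histogram = function() histogram_features(cube),
              perception = function() perception_features(cube, cfg),
              lbp = function() lbp_features(cube, cfg),
              lpq = function() lpq_features(cube, cfg),
              bsif = function() bsif_features(cube, cfg))
  out <- lapply(descriptors, function(d) fns[[d]]())
  names(out) <- descriptors
  out
}
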