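#' Construct a multispectral image cube
#'
#' A spectral cube is an H x W x B stack of co-registered single-band images
#' of one tissue field, each band captured at a different centre wavelength.
#' Bands are tagged with the part of the light spectrum they come from:
#' `"VS"` (visual) or `"IRS"` (infrared).
#'
#' @param pixels numeric H x W x B array of non-negative finite intensities.
#'   A matrix is promoted to a single-band cube.
#' @param wavelengths_nm numeric vector of length B, centre wavelength of each
#'   band in nanometres; must be strictly increasing within each spectrum tag.
#' @param spectrum_tags character vector of length B, each `"VS"` or `"IRS"`.
#' @param cube_id character scalar identifying the cube.
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(pixels, wavelengths_nm, spectrum_tags, cube_id = "cube") {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  b <- dim(pixels)[3L]
  if (length(wavelengths_nm) != b || length(spectrum_tags) != b)
    stop("metadata error: ", b, " bands but ", length(wavelengths_nm),
         " wavelengths and ", length(spectrum_tags), " spectrum tags")
  if (!all(spectrum_tags %in% c("VS", "IRS")))
    stop("metadata error: spectrum tags must be 'VS' or 'IRS'")
  if (anyNA(pixels) || !all(is.finite(pixels)) || any(pixels < 0))
    stop("intensity error: all intensities must be finite and non-negative")
  for (tag in unique(spectrum_tags)) {
    wl <- wavelengths_nm[spectrum_tags == tag]
    if (length(wl) > 1L && any(diff(wl) <= 0))
      stop("metadata error: wavelengths must be strictly increasing within ", tag)
  }
  structure(
    list(pixels = pixels * 1.0, wavelengths_nm = as.numeric(wavelengths_nm),
         spectrum_tags = as.character(spectrum_tags), cube_id = as.character(cube_id)),
    class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("spectral_cube '%s': %d x %d pixels, %d bands (%d VS, %d IRS)\n",
              x$cube_id, d[1], d[2], d[3],
              sum(x$spectrum_tags == "VS"), sum(x$spectrum_tags == "IRS")))
  cat(sprintf("  wavelengths: %g-%g nm; intensity range [%g, %g]\n",
              min(x$wavelengths_nm), max(x$wavelengths_nm),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$pixels)

#' Number of bands in a cube
#' @param cube a `spectral_cube`.
#' @return integer band count.
#' @export
n_bands <- function(cube) dim(cube$pixels)[3L]

#' Restrict a cube to a subset of bands
#' @param cube a `spectral_cube`.
#' @param bands integer vector of band indices (1-based) to keep, in order.
#' @return a `spectral_cube` with the selected bands.
#' @export
subset_bands <- function(cube, bands) {
  b <- n_bands(cube)
  if (any(bands < 1L | bands > b)) stop("band subset out of range 1..", b)
  # selections may be in greedy (non-wavelength) order, so the subset is
  # built directly rather than re-validated for wavelength monotonicity
  out <- cube
  out$pixels <- cube$pixels[, , bands, drop = FALSE]
  out$wavelengths_nm <- cube$wavelengths_nm[bands]
  out$spectrum_tags <- cube$spectrum_tags[bands]
  out
}

#' Read a multispectral cube from disk
#'
#' Reads either a multi-page TIFF (one page per band, page k -> band k) or a
#' directory of equally sized single-band images (PNG or TIFF, taken in
#' lexicographic filename order). Intensities are returned as stored, cast to
#' double, with no rescaling: 16-bit TIFF pages yield their integer sample
#' values; 8-bit PNG files yield integers in 0..255.
#'
#' @param path path to a multi-page TIFF file or a directory of band images.
#' @param wavelengths_nm,spectrum_tags per-band metadata, length must equal
#'   the number of pages/files found.
#' @param cube_id identifier for the cube; defaults to the file/dir name.
#' @return a `spectral_cube`.
#' @export
read_cube <- function(path, wavelengths_nm, spectrum_tags,
                      cube_id = basename(path)) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("format error: no band images in ", path)
    pages <- lapply(files, read_band_image)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, band_to_matrix)
  }
  if (length(pages) != length(wavelengths_nm))
    stop("metadata error: ", length(pages), " pages but ",
         length(wavelengths_nm), " wavelengths")
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("format error: band images have non-uniform sizes")
  px <- array(0, c(dims[1, 1], dims[2, 1], length(pages)))
  for (k in seq_along(pages)) px[, , k] <- pages[[k]]
  spectral_cube(px, wavelengths_nm, spectrum_tags, cube_id)
}

read_band_image <- function(f) {
  if (grepl("\\.png$", f, ignore.case = TRUE)) {
    # readPNG rescales to [0,1]; undo the 8-bit scaling (the format this
    # package itself writes for band directories)
    band_to_matrix(png::readPNG(f)) * 255
  } else {
    band_to_matrix(tiff::readTIFF(f, as.is = TRUE))
  }
}

band_to_matrix <- function(p) {
  if (length(dim(p)) == 3L) p <- p[, , 1L]  # grey stored with channels
  storage.mode(p) <- "double"
  p
}

#' Write a cube as a multi-page 16-bit TIFF
#'
#' One page per band. Intensities must lie in 0..65535; integer-valued cubes
#' round-trip bit-exactly through [read_cube()].
#'
#' @param cube a `spectral_cube`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  if (max(cube$pixels) > 65535)
    stop("intensity error: 16-bit TIFF output requires intensities <= 65535")
  pages <- lapply(seq_len(n_bands(cube)),
                  function(k) cube$pixels[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Attach a class label and provenance to a cube
#'
#' @param cube a `spectral_cube`.
#' @param label class label (e.g. NORMAL, HP, TA_LG, CA).
#' @param patient_id,slide_id identifiers of the patient and biopsy slide the
#'   image came from; used by the patient-level ("strong") fold protocol.
#' @param parent_image_id identifier of the whole image this sample was tiled
#'   from (defaults to the cube's own id).
#' @param tile_index 1-based row-major tile position within the parent image.
#' @return an object of class `labeled_sample`.
#' @export
labeled_sample <- function(cube, label, patient_id, slide_id,
                           parent_image_id = cube$cube_id, tile_index = 1L) {
  stopifnot(inherits(cube, "spectral_cube"))
  structure(list(cube = cube, label = as.character(label),
                 patient_id = as.character(patient_id),
                 slide_id = as.character(slide_id),
                 parent_image_id = as.character(parent_image_id),
                 tile_index = as.integer(tile_index)),
            class = "labeled_sample")
}

#' Split a labelled image into non-overlapping sub-images
#'
#' Whole images are divided into a regular grid of tiles; each tile inherits
#' the whole image's label, patient and slide, and records its parent image
#' and row-major tile index so that predictions can later be aggregated back
#' to the whole image.
#'
#' @param sample a `labeled_sample`.
#' @param tile_h,tile_w tile height and width in pixels; must divide the image
#'   height and width exactly (no partial tiles).
#' @return list of `labeled_sample` tiles in row-major order.
#' @export
tile_cube <- function(sample, tile_h, tile_w) {
  stopifnot(inherits(sample, "labeled_sample"))
  d <- dim(sample$cube$pixels)
  if (d[1] %% tile_h != 0L || d[2] %% tile_w != 0L)
    stop(sprintf("tiling error: %dx%d image not divisible by %dx%d tiles",
                 d[1], d[2], tile_h, tile_w))
  nr <- d[1] %/% tile_h
  nc <- d[2] %/% tile_w
  out <- vector("list", nr * nc)
  idx <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      idx <- idx + 1L
      px <- sample$cube$pixels[((i - 1L) * tile_h + 1L):(i * tile_h),
                               ((j - 1L) * tile_w + 1L):(j * tile_w), ,
                               drop = FALSE]
      tc <- spectral_cube(px, sample$cube$wavelengths_nm,
                          sample$cube$spectrum_tags,
                          sprintf("%s_t%02d", sample$cube$cube_id, idx))
      out[[idx]] <- labeled_sample(tc, sample$label, sample$patient_id,
                                   sample$slide_id,
                                   parent_image_id = sample$cube$cube_id,
                                   tile_index = idx)
    }
  }
  out
}

#' Read a dataset manifest
#'
#' The manifest is a CSV with columns `cube_path`, `label`, `patient_id`,
#' `slide_id` (one row per whole image); per-band wavelength metadata lives in
#' a sidecar CSV with columns `band_index`, `wavelength_nm`, `spectrum_tag`.
#'
#' @param manifest_csv path to the manifest CSV.
#' @param bands_csv path to the band-metadata sidecar CSV.
#' @param class_set optional ordered class names; defaults to the sorted
#'   unique labels present.
#' @return a `data.frame` of class `ms_manifest` with attributes `class_set`,
#'   `wavelengths_nm` and `spectrum_tags`.
#' @export
read_manifest <- function(manifest_csv, bands_csv, class_set = NULL) {
  man <- utils::read.csv(manifest_csv, stringsAsFactors = FALSE)
  need <- c("cube_path", "label", "patient_id", "slide_id")
  if (!all(need %in% names(man)))
    stop("manifest error: missing columns ",
         paste(setdiff(need, names(man)), collapse = ", "))
  bands <- utils::read.csv(bands_csv, stringsAsFactors = FALSE)
  bands <- bands[order(bands$band_index), ]
  as_manifest(man, class_set %||% sort(unique(man$label)),
              bands$wavelength_nm, bands$spectrum_tag)
}

as_manifest <- function(df, class_set, wavelengths_nm, spectrum_tags) {
  if (!all(df$label %in% class_set))
    stop("manifest error: labels outside the declared class set: ",
         paste(setdiff(df$label, class_set), collapse = ", "))
  # a patient's slides must be consistent: every slide belongs to one patient
  sp <- unique(df[, c("patient_id", "slide_id")])
  dup <- sp$slide_id[duplicated(sp$slide_id)]
  if (length(dup))
    stop("manifest error: slide(s) shared by several patients: ",
         paste(unique(dup), collapse = ", "))
  structure(df, class_set = as.character(class_set),
            wavelengths_nm = as.numeric(wavelengths_nm),
            spectrum_tags = as.character(spectrum_tags),
            class = c("ms_manifest", "data.frame"))
}

#' @export
print.ms_manifest <- function(x, ...) {
  cat(sprintf("ms_manifest: %d images, %d patients, classes: %s\n",
              nrow(x), length(unique(x$patient_id)),
              paste(attr(x, "class_set"), collapse = ", ")))
  print(table(x$label))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
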