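#' Configuration of the synthetic multispectral dataset generator
#'
#' The generator emulates the structure of a multispectral colorectal
#' histopathology dataset: balanced classes of whole images owned by
#' patients (each patient one diagnosis, 1-3 biopsy slides), visual-spectrum
#' bands with high contrast and low noise next to infrared bands with lower
#' contrast, class-specific spectral responses, patient-level intensity and
#' texture offsets, and per-class texture families (round gland lattices for
#' normal tissue, serrated elongated stripes for hyperplastic polyps,
#' crowded distorted tubes for low-grade tubular adenoma, high-disorder
#' fragments for carcinoma).
#'
#' @param n_patients number of patients; classes are assigned round-robin so
#'   the class frequencies stay balanced. Every patient has one class
#'   (biopsy-level labelling).
#' @param images_per_patient whole images per patient.
#' @param class_set ordered class names (default the four-class colorectal
#'   set).
#' @param H,W whole-image size in pixels.
#' @param vs_wavelengths_nm,irs_wavelengths_nm band wavelength grids
#'   (defaults: 13 visual bands 470-710 nm and 26 infrared bands
#'   1150-1650 nm, 20 nm apart).
#' @param texture_scale base texture feature wavelength in pixels.
#' @param contrast_vs,contrast_irs texture contrast of VS and IRS bands.
#' @param class_sep amplitude of the class-specific per-band mean offsets;
#'   the first VS and the first IRS band are deliberately left flat
#'   (uninformative) as negative controls for band ranking.
#' @param patient_effect_sd standard deviation of the patient-specific
#'   intensity offset; also scales the patient-specific texture phase and
#'   orientation offsets. 0 makes same-class cubes of different patients
#'   identical when `noise_sd = 0`.
#' @param noise_sd pixel noise standard deviation on VS bands (IRS bands get
#'   twice this, emulating their lower SNR).
#' @param mixed_labels if `TRUE`, a fifth of the whole images are composites
#'   whose left half shows a second (less abnormal) class while keeping the
#'   more abnormal whole-image label.
#' @param seed root seed; every patient/image draws from a derived
#'   substream, so the dataset is reproducible cube by cube.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 40L, images_per_patient = 5L,
                         class_set = c("NORMAL", "HP", "TA_LG", "CA"),
                         H = 256L, W = 320L,
                         vs_wavelengths_nm = seq(470, 710, by = 20),
                         irs_wavelengths_nm = seq(1150, 1650, by = 20),
                         texture_scale = 16,
                         contrast_vs = 0.35, contrast_irs = 0.15,
                         class_sep = 0.08,
                         patient_effect_sd = 0.08, noise_sd = 0.04,
                         mixed_labels = FALSE, seed = 1L) {
  structure(as.list(environment()), class = "synth_config")
}

# deterministic substream seed below 2^31
substream_seed <- function(root, ...) {
  ids <- c(...)
  s <- as.numeric(root) %% 2147483647
  for (i in ids) s <- (s * 48271 + as.numeric(i) * 8191 + 1) %% 2147483647
  as.integer(s)
}

#' Generate a synthetic multispectral dataset
#'
#' @param cfg a [synth_config()].
#' @param out_dir optional directory; when given, every cube is written as a
#'   multi-page 16-bit TIFF alongside `manifest.csv` and `bands.csv`, the
#'   layout [read_manifest()] consumes. Intensities are integer-valued
#'   (camera-count style), so regeneration is byte-identical.
#' @return list with `manifest` (an `ms_manifest`; column `cube_id`, plus
#'   `cube_path` when written) and `cubes` (named list of `spectral_cube`).
#' @export
generate_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  wl <- c(cfg$vs_wavelengths_nm, cfg$irs_wavelengths_nm)
  tags <- rep(c("VS", "IRS"),
              c(length(cfg$vs_wavelengths_nm), length(cfg$irs_wavelengths_nm)))
  ncls <- length(cfg$class_set)
  rows <- list(); cubes <- list()
  for (p in seq_len(cfg$n_patients)) {
    cl <- cfg$class_set[(p - 1L) %% ncls + 1L]
    pid <- sprintf("P%03d", p)
    pp <- with_local_seed(substream_seed(cfg$seed, 1L, p), {
      list(offset = stats::rnorm(1, 0, cfg$patient_effect_sd),
           phase = stats::runif(2, 0, 2 * pi) * min(1, 10 * cfg$patient_effect_sd),
           angle = stats::runif(1, -0.35, 0.35) * min(1, 10 * cfg$patient_effect_sd),
           n_slides = sample(1:3, 1, prob = c(0.8, 0.15, 0.05)))
    })
    for (im in seq_len(cfg$images_per_patient)) {
      iid <- sprintf("%s_I%02d", pid, im)
      slide <- sprintf("%s_S%d", pid, (im - 1L) %% pp$n_slides + 1L)
      cube <- with_local_seed(substream_seed(cfg$seed, 2L, p, im),
                              render_cube(cfg, cl, pp, wl, tags, iid))
      rows[[iid]] <- data.frame(cube_id = iid, label = cube$label,
                                patient_id = pid, slide_id = slide,
                                stringsAsFactors = FALSE)
      cubes[[iid]] <- cube$cube
    }
  }
  man <- do.call(rbind, rows)
  rownames(man) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    man$cube_path <- file.path(out_dir, paste0(man$cube_id, ".tif"))
    for (i in seq_len(nrow(man))) write_cube(cubes[[man$cube_id[i]]],
                                             man$cube_path[i])
    utils::write.csv(man, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(band_index = seq_along(wl),
                                wavelength_nm = wl, spectrum_tag = tags),
                     file.path(out_dir, "bands.csv"), row.names = FALSE)
  }
  list(manifest = as_manifest(man, cfg$class_set, wl, tags), cubes = cubes)
}

# one whole image: class texture field modulated per band, integer counts
render_cube <- function(cfg, cl, pp, wl, tags, iid) {
  label <- cl
  tex <- class_texture(cl, cfg, pp)
  if (cfg$mixed_labels && stats::runif(1) < 0.2) {
    other <- cfg$class_set[max(1L, match(cl, cfg$class_set) - 1L)]
    if (other != cl) {
      tex2 <- class_texture(other, cfg, pp)
      half <- seq_len(cfg$W %/% 2L)
      tex[, half] <- tex2[, half]   # label stays the more abnormal class
    }
  }
  b <- length(wl)
  px <- array(0, c(cfg$H, cfg$W, b))
  ci <- match(cl, cfg$class_set)
  for (k in seq_len(b)) {
    vs <- tags[k] == "VS"
    contrast <- if (vs) cfg$contrast_vs else
      cfg$contrast_irs * (0.7 + 0.3 * sin(2 * pi * k / b + ci))
    # class-specific mean spectrum; first band of each spectrum left flat
    flat <- k == 1L || k == which(tags == "IRS")[1]
    mu <- 0.55 + if (flat) 0 else
      cfg$class_sep * sin(2 * pi * (k / b) * ci + ci)
    nsd <- if (vs) cfg$noise_sd else 2 * cfg$noise_sd
    band <- mu + pp$offset + contrast * tex
    if (nsd > 0) band <- band + matrix(stats::rnorm(cfg$H * cfg$W, 0, nsd),
                                       cfg$H, cfg$W)
    px[, , k] <- pmax(band, 0)
  }
  px <- round(px * 4000)  # integer camera counts
  list(cube = spectral_cube(px, wl, tags, iid), label = label)
}

# class texture fields in roughly [-1, 1] on the H x W grid
class_texture <- function(cl, cfg, pp) {
  H <- cfg$H; W <- cfg$W; s <- cfg$texture_scale
  ang <- pp$angle
  x <- outer(rep(1, H), seq_len(W)); y <- outer(seq_len(H), rep(1, W))
  xr <- cos(ang) * x - sin(ang) * y
  yr <- sin(ang) * x + cos(ang) * y
  switch(cl,
    NORMAL = sin(2 * pi * xr / s + pp$phase[1]) *
             sin(2 * pi * yr / s + pp$phase[2]),
    HP = sin(2 * pi * yr / (0.75 * s) + pp$phase[1] +
               2 * sin(2 * pi * xr / (0.5 * s) + pp$phase[2])),
    TA_LG = sin(2 * pi * yr / (0.45 * s) + pp$phase[1] +
                  3 * smooth_field(H, W, s)),
    CA = tanh(3 * smooth_field(H, W, 0.6 * s)),
    # extra classes beyond the canonical four: oriented gratings
    sin(2 * pi * (xr + yr) / s + pp$phase[1]))
}

# smooth unit-variance random field with correlation length ~ scale
smooth_field <- function(H, W, scale) {
  side <- max(H, W)
  z <- matrix(stats::rnorm(side^2), side)
  fr <- c(0:(side %/% 2), -((side - (side %/% 2 + 1)):1)) / side
  g <- exp(-0.5 * (outer(fr^2, fr^2, `+`)) * scale^2 * 4)
  f <- Re(stats::fft(stats::fft(z) * g, inverse = TRUE)) / side^2
  f <- f[seq_len(H), seq_len(W), drop = FALSE]
  (f - mean(f)) / stats::sd(f)
}

#' Cubes with known linear band redundancy
#'
#' Ground truth for band-selection tests: `b_independent` bands are
#' independent smooth random fields; `b_derived` further bands are fixed
#' affine combinations of the independent ones (plus optional noise).
#' Greedy linear-prediction selection must pick the independent bands before
#' any derived band.
#'
#' @param b_independent number of independent bands (>= 2).
#' @param b_derived number of linearly derived bands.
#' @param seed root seed.
#' @param n_samples number of cubes.
#' @param H,W cube size.
#' @param noise_sd noise added to the derived bands (0 = exact combinations).
#' @return list with `cubes` (list of `spectral_cube`; derived bands come
#'   last) and `weights` (the mixing matrix used).
#' @export
generate_band_redundancy_case <- function(b_independent, b_derived, seed = 1L,
                                          n_samples = 3L, H = 32L, W = 32L,
                                          noise_sd = 0) {
  if (b_independent < 2)
    stop("config error: need at least 2 independent bands")
  b <- b_independent + b_derived
  Wmix <- with_local_seed(substream_seed(seed, 9L), {
    m <- matrix(stats::runif(b_derived * b_independent, 0.2, 1), b_derived)
    m / rowSums(m)
  })
  cubes <- lapply(seq_len(n_samples), function(i) {
    px <- array(0, c(H, W, b))
    with_local_seed(substream_seed(seed, 10L, i), {
      for (k in seq_len(b_independent))
        px[, , k] <- smooth_field(H, W, 6) + 3
      for (j in seq_len(b_derived)) {
        mix <- 0
        for (k in seq_len(b_independent))
          mix <- mix + Wmix[j, k] * px[, , k]
        if (noise_sd > 0)
          mix <- mix + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
        px[, , b_independent + j] <- mix
      }
    })
    spectral_cube(pmax(px, 0), 400 + 20 * seq_len(b), rep("VS", b),
                  sprintf("redundant_%02d", i))
  })
  list(cubes = cubes, weights = Wmix)
}
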