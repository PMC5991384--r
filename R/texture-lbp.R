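#' Rotation-invariant local binary patterns
#'
#' Per band: circular LBP codes in the (P, R) = (16, 2) configuration --
#' 16 neighbours on a radius-2 circle, sampled with bilinear interpolation,
#' each set to 1 where the neighbour intensity is >= the centre intensity --
#' mapped to rotation-invariant classes (the minimum of the code over all 16
#' circular bit rotations) and histogrammed over all pixels with a full
#' neighbourhood. For P = 16 there are exactly 4116 rotation classes, so the
#' per-band block has 4116 bins.
#'
#' @param cube a `spectral_cube`.
#' @param cfg a [descriptor_config()].
#' @return `feature_vector`; bins hold raw pixel counts.
#' @export
lbp_features <- function(cube, cfg = descriptor_config()) {
  d <- dim(cube$pixels)
  P <- cfg$lbp_neighbors; R <- cfg$lbp_radius
  if (d[1] <= 2 * R || d[2] <= 2 * R)
    stop("config error: band smaller than the LBP neighbourhood")
  map <- lbp_ri_map(P)
  nb <- max(map)  # number of rotation-invariant classes
  vals <- vapply(seq_len(d[3]), function(k) {
    codes <- lbp_codes(cube$pixels[, , k], P, R)
    tabulate(map[codes + 1L], nbins = nb)
  }, numeric(nb))
  feature_vector("lbp", as.numeric(vals), nb, d[3])
}

#' Rotation-invariant code mapping for P-bit circular codes
#'
#' Maps every P-bit code 0..2^P-1 to a 1-based class index; two codes share a
#' class iff one is a circular bit rotation of the other. Class indices are
#' assigned in increasing order of the minimal rotation, so the class count
#' equals the number of binary necklaces of length P (4116 for P = 16).
#' The table for a given P is computed once and cached.
#'
#' @param P number of neighbours (code length in bits).
#' @return integer vector of length 2^P; `map[code + 1]` is the class.
#' @export
lbp_ri_map <- function(P = 16L) {
  key <- paste0("ri", P)
  if (!is.null(.ms_cache[[key]])) return(.ms_cache[[key]])
  codes <- 0:(2^P - 1)
  mn <- codes
  mask <- 2^P - 1
  for (r in 1:(P - 1)) {
    rot <- bitwOr(bitwShiftR(codes, r),
                  bitwAnd(bitwShiftL(codes, P - r), mask))
    mn <- pmin(mn, rot)
  }
  map <- match(mn, sort(unique(mn)))
  .ms_cache[[key]] <- map
  map
}

.ms_cache <- new.env(parent = emptyenv())

# raw LBP codes (integer vector) for all pixels with a full neighbourhood
lbp_codes <- function(band, P, R) {
  H <- nrow(band); W <- ncol(band)
  m <- ceiling(R)
  rows <- (m + 1):(H - m); cols <- (m + 1):(W - m)
  centre <- band[rows, cols]
  codes <- matrix(0, length(rows), length(cols))
  for (p in 0:(P - 1)) {
    ang <- 2 * pi * p / P
    # image coordinates: +row is down; sample at (-R sin, R cos) keeps the
    # neighbour ring counter-clockwise from the +column axis
    dr <- round(-R * sin(ang), 9); dc <- round(R * cos(ang), 9)
    nb <- bilinear_shift(band, rows, cols, dr, dc)
    codes <- codes + 2^p * (nb >= centre)
  }
  as.integer(codes)
}

# bilinear sample of band at (rows + dr, cols + dc), vectorized over the grid
bilinear_shift <- function(band, rows, cols, dr, dc) {
  r0 <- floor(dr); c0 <- floor(dc)
  fr <- dr - r0; fc <- dc - c0
  g <- function(ro, co) band[rows + ro, cols + co, drop = FALSE]
  base <- g(r0, c0)
  if (fr < 1e-9 && fc < 1e-9) return(base)
  # anchored form: constant neighbourhoods interpolate to exactly the base
  # value, keeping the >= comparison stable on flat regions
  base + (1 - fr) * fc * (g(r0, c0 + 1) - base) +
    fr * (1 - fc) * (g(r0 + 1, c0) - base) +
    fr * fc * (g(r0 + 1, c0 + 1) - base)
}
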