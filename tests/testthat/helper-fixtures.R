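# shared fixture builders; everything is generated in code at test time

make_cube <- function(H = 32, W = 32, b = 3, seed = 1, id = "fix",
                      tags = NULL, wl = NULL) {
  set.seed(seed)
  px <- array(stats::runif(H * W * b) * 100, c(H, W, b))
  tags <- tags %||% rep("VS", b)
  if (is.null(wl)) {
    wl <- numeric(b)
    wl[tags == "VS"] <- seq(470, by = 20, length.out = sum(tags == "VS"))
    wl[tags == "IRS"] <- seq(1150, by = 20, length.out = sum(tags == "IRS"))
  }
  spectral_cube(px, wl, tags, id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# counter-clockwise quarter turn of a matrix
rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]

# small labelled manifest without cubes, for fold-protocol tests
toy_manifest <- function(n_patients = 8, images_per_patient = 3,
                         classes = c("NORMAL", "HP", "TA_LG", "CA")) {
  rows <- do.call(rbind, lapply(seq_len(n_patients), function(p) {
    data.frame(cube_id = sprintf("P%02d_I%02d", p, seq_len(images_per_patient)),
               label = classes[(p - 1) %% length(classes) + 1],
               patient_id = sprintf("P%02d", p),
               slide_id = sprintf("P%02d_S1", p),
               stringsAsFactors = FALSE)
  }))
  mshisto:::as_manifest(rows, classes, c(470, 1150), c("VS", "IRS"))
}

# feature-level multiclass toy: each "descriptor" carries the signal for a
# different split of the classes, plus a pure-noise descriptor
block_informative_features <- function(n_per_class = 12, seed = 1,
                                       noise = 0.4) {
  set.seed(seed)
  classes <- c("A", "B", "C", "D")
  y <- rep(classes, each = n_per_class)
  n <- length(y)
  d1 <- cbind((y %in% c("A", "B")) * 2 - 1, (y == "A") * 2 - 1) +
    matrix(rnorm(2 * n, 0, noise), n)
  d2 <- cbind((y == "C") * 2 - 1) + matrix(rnorm(n, 0, noise), n)
  d3 <- matrix(rnorm(3 * n), n)
  list(features = list(split_ab = d1, split_cd = d2, noise = d3), labels = y)
}
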