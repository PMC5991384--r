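test_that("per-band block lengths follow the descriptor contracts", {
  cb <- make_cube(H = 32, W = 32, b = 3, tags = c("VS", "VS", "IRS"))
  fv <- extract_all(cb)
  expect_named(fv, descriptor_names())
  blocks <- vapply(fv, function(v) v$band_block_size, integer(1))
  expect_equal(unname(blocks), c(20L, 11L, 5L, 4116L, 256L, 1024L))
  expect_equal(unname(vapply(fv, length, integer(1))), 3L * blocks,
               ignore_attr = TRUE)
  # one selected band -> exactly one block
  f1 <- extract_all(cb, band_subset = 2)
  expect_equal(unname(vapply(f1, length, integer(1))),
               c(20L, 11L, 5L, 4116L, 256L, 1024L))
  expect_error(extract_all(cb, descriptors = "gabor"), "unknown descriptor")
})

test_that("permuting band order permutes feature blocks identically", {
  cb <- make_cube(H = 32, W = 32, b = 3, seed = 9)
  perm <- c(3, 1, 2)
  for (d in c("glcm", "histogram", "perception", "bsif")) {
    a <- extract_all(cb, descriptors = d)[[d]]
    b <- extract_all(subset_bands(cb, perm), descriptors = d)[[d]]
    for (k in seq_along(perm))
      expect_equal(band_block(b, k), band_block(a, perm[k]))
  }
})

test_that("GLCM statistics match a brute-force co-occurrence oracle", {
  board <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)  # checkerboard
  cb <- spectral_cube(array(board, c(4, 4, 1)), 470, "VS")
  cfg <- descriptor_config(glcm_displacements = 1)
  got <- band_block(glcm_features(cb, cfg), 1)

  # oracle: enumerate every pixel pair at distance 1 for the 4 angles
  L <- 32
  q <- ifelse(board > 0, 32, 1)
  counts <- matrix(0, L, L)
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  for (off in offsets) for (i in 1:4) for (j in 1:4) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 >= 1 && i2 <= 4 && j2 >= 1 && j2 <= 4) {
      counts[q[i, j], q[i2, j2]] <- counts[q[i, j], q[i2, j2]] + 1
      counts[q[i2, j2], q[i, j]] <- counts[q[i2, j2], q[i, j]] + 1
    }
  }
  P <- counts / sum(counts)
  i <- row(P); j <- col(P)
  mi <- sum(i * P); mj <- sum(j * P)
  oracle <- c(sum(P^2), sum((i - j)^2 * P), sum(P / (1 + abs(i - j))),
              sum((i - mi) * (j - mj) * P) /
                sqrt(sum((i - mi)^2 * P) * sum((j - mj)^2 * P)))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("GLCM conventions hold on constant bands and 90-degree rotations", {
  const <- spectral_cube(array(7, c(8, 8, 1)), 470, "VS")
  g <- band_block(glcm_features(const), 1)
  # energy 1, contrast 0, homogeneity 1, correlation 1 for each displacement
  expect_equal(g, rep(c(1, 0, 1, 1), 5))
  set.seed(21)
  band <- matrix(runif(100), 10, 10)
  c1 <- spectral_cube(array(band, c(10, 10, 1)), 470, "VS")
  c2 <- spectral_cube(array(rot90(band), c(10, 10, 1)), 470, "VS")
  cfg <- descriptor_config(glcm_displacements = 1:3)
  expect_equal(band_block(glcm_features(c1, cfg), 1),
               band_block(glcm_features(c2, cfg), 1), tolerance = 1e-12)
  expect_error(glcm_features(c1, descriptor_config(glcm_displacements = 10)),
               "config error")
})

test_that("intensity statistics match direct moment summation", {
  cb <- spectral_cube(array(c(0, 0, 1, 1), c(2, 2, 1)), 470, "VS")
  h <- band_block(histogram_features(cb), 1)
  # mean .5, var .25, skewness 0, kurtosis 1, central moments 5..11
  expect_equal(h, c(0.5, 0.25, 0, 1,
                    0, 0.5^6, 0, 0.5^8, 0, 0.5^10, 0))
  hc <- band_block(histogram_features(
    spectral_cube(array(3, c(4, 4, 1)), 470, "VS")), 1)
  expect_equal(hc, c(3, rep(0, 10)))
  # against independent summation on random data
  set.seed(4)
  x <- runif(36)
  cb2 <- spectral_cube(array(x, c(6, 6, 1)), 470, "VS")
  h2 <- band_block(histogram_features(cb2), 1)
  m <- mean(x); cm <- sapply(2:11, function(p) mean((x - m)^p))
  expect_equal(h2, c(m, cm[1], cm[2] / cm[1]^1.5, cm[3] / cm[1]^2, cm[4:10]),
               tolerance = 1e-12)
})

test_that("perception features behave like Tamura statistics", {
  stripes <- matrix(rep(c(0, 0, 1, 1), length.out = 64 * 64), 64, 64)
  c1 <- spectral_cube(array(stripes, c(64, 64, 1)), 470, "VS")
  c2 <- spectral_cube(array(t(stripes), c(64, 64, 1)), 470, "VS")
  p1 <- band_block(perception_features(c1), 1)
  p2 <- band_block(perception_features(c2), 1)
  # coarseness and contrast identical; roughness = coarseness + contrast
  expect_equal(p1[c(1, 5)], p2[c(1, 5)])
  expect_equal(p1[4], p1[1] + p1[5])
  # the dominant gradient orientation moves by 90 degrees (8 of 16 bins)
  h1 <- mshisto:::tamura_orientation_hist(stripes)
  h2 <- mshisto:::tamura_orientation_hist(t(stripes))
  expect_equal(sum(h1), sum(h2))
  expect_equal((which.max(h1) - 1 + 8) %% 16, which.max(h2) - 1)
  const <- spectral_cube(array(2, c(32, 32, 1)), 470, "VS")
  expect_equal(band_block(perception_features(const), 1)[5], 0)  # contrast
  expect_error(perception_features(make_cube(16, 16, 1)), "config error")
})

test_that("riLBP has 4116 classes and is exactly 90-degree invariant", {
  map <- lbp_ri_map(16L)
  expect_equal(max(map), 4116L)   # binary necklaces of length 16
  expect_equal(length(map), 65536L)
  # constant band: all-ones code via the >= convention, single bin
  const <- spectral_cube(array(5, c(16, 16, 1)), 470, "VS")
  h <- band_block(lbp_features(const), 1)
  expect_equal(which(h > 0), 4116L)
  expect_equal(sum(h), 12 * 12)
  set.seed(6)
  band <- matrix(runif(48 * 48), 48, 48)
  h1 <- band_block(lbp_features(
    spectral_cube(array(band, c(48, 48, 1)), 470, "VS")), 1)
  h2 <- band_block(lbp_features(
    spectral_cube(array(rot90(band), c(48, 48, 1)), 470, "VS")), 1)
  expect_equal(h1, h2)
})

test_that("riLPQ conserves mass and tolerates rotation", {
  set.seed(8)
  band <- matrix(0, 48, 48)
  for (i in 1:48) for (j in 1:48)
    band[i, j] <- sin(i / 4) + cos(j / 5) + sin((i + j) / 7)
  band <- band - min(band)
  c1 <- spectral_cube(array(band, c(48, 48, 1)), 470, "VS")
  h1 <- band_block(lpq_features(c1), 1)
  expect_equal(sum(h1), (48 - 14)^2)  # histogram conservation
  c2 <- spectral_cube(array(rot90(band), c(48, 48, 1)), 470, "VS")
  h2 <- band_block(lpq_features(c2), 1)
  expect_lt(sum(abs(h1 - h2)), 0.05 * sum(h1))
  expect_error(lpq_features(make_cube(10, 10, 1)), "config error")
})

test_that("BSIF codes match a manual convolution oracle", {
  # 2-filter toy bank on a 3x3 image -> a single coded pixel
  bank <- array(0, c(3, 3, 2))
  bank[, , 1] <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3)   # laplacian-like
  bank[, , 2] <- matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3) # vertical edge
  img <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 10), 3, 3)
  cb <- spectral_cube(array(img, c(3, 3, 1)), 470, "VS")
  cfg <- descriptor_config(bsif_filter_size = 3L, bsif_filter_count = 2L,
                           bsif_filter_bank = bank)
  h <- band_block(bsif_features(cb, cfg), 1)
  r1 <- sum(bank[, , 1] * img); r2 <- sum(bank[, , 2] * img)
  code <- (r1 > 0) + 2 * (r2 > 0)
  oracle <- numeric(4); oracle[code + 1] <- 1
  expect_equal(h, oracle)
  # default bank: zero-mean filters put a constant band in the zero code
  cc <- spectral_cube(array(4, c(16, 16, 1)), 470, "VS")
  hc <- band_block(bsif_features(cc), 1)
  expect_equal(which(hc > 0), 1L)
  expect_equal(sum(hc), 10 * 10)
  bank0 <- bsif_default_bank()
  expect_equal(dim(bank0), c(7L, 7L, 10L))
  expect_lt(max(abs(apply(bank0, 3, sum))), 1e-8)
  expect_error(bsif_features(cb, descriptor_config(bsif_filter_bank = bank)),
               "config error")
})

test_that("histogram descriptors count every coded pixel once", {
  cb <- make_cube(H = 24, W = 20, b = 2, seed = 13)
  fv <- extract_all(cb, descriptors = c("lbp", "lpq", "bsif"))
  for (k in 1:2) {
    expect_equal(sum(band_block(fv$lbp, k)), 20 * 16)
    expect_equal(sum(band_block(fv$lpq, k)), 10 * 6)
    expect_equal(sum(band_block(fv$bsif, k)), 18 * 14)
    expect_true(all(band_block(fv$lbp, k) >= 0))
  }
})
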