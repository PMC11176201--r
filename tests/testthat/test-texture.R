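# a single fully-masked 5x5 slice: exactly one qualifying 5x5 window at
# min fraction 1, so the windowed path must equal a direct GLCM
test_that("the windowed kernel agrees with the direct GLCM on one window", {
  set.seed(31)
  for (rep in 1:10) {
    a2 <- matrix(rnorm(25, 100, 20), 5, 5)
    img <- volume_image(array(a2, c(5, 5, 1)))
    msk <- wall_mask(array(1L, c(5, 5, 1)), img, check_hollow = FALSE)
    cfg <- texture_config(angles = c(0, 45, 90, 135), distances = 1,
                          bins = 4, windows = 5, min_mask_fraction = 1,
                          range_policy = "full")
    tx <- windowed_texture(img, msk, cfg)
    lev <- quantize(a2, 4, range = range(a2))
    for (a in c(0, 45, 90, 135)) {
      g <- glcm(lev, angle = a, distance = 1, nbins = 4)
      h <- haralick(g)
      got <- tx[sprintf("%s_a%d_d1_b4_w5", names(h), a)]
      expect_equal(unname(got), unname(h), tolerance = 1e-12)
    }
  }
})

test_that("a homogeneous wall yields zero contrast and unit energy", {
  sh <- box_shell(3L, 9L, 12L)
  img <- volume_image(array(100, c(12, 12, 12)))
  tx <- windowed_texture(img, sh$mask,
                         texture_config(distances = 1, bins = c(8, 16),
                                        windows = 5))
  expect_true(all(abs(tx[grep("^contrast", names(tx))]) < 1e-12))
  expect_true(all(abs(tx[grep("^energy", names(tx))] - 1) < 1e-12))
  expect_true(all(abs(tx[grep("^entropy", names(tx))]) < 1e-12))
})

test_that("a mask thinner than every window yields sentinel columns", {
  img <- volume_image(array(rnorm(12^3), c(12, 12, 12)))
  thin <- array(0L, c(12, 12, 12)); thin[6, 3:9, 3:9] <- 1L
  msk <- wall_mask(thin, img, check_hollow = FALSE)
  cfg <- texture_config(angles = 0, distances = 1, bins = 8, windows = 9,
                        min_mask_fraction = 1)
  tx <- windowed_texture(img, msk, cfg)
  expect_true(all(is.na(tx)))
})

test_that("angle-aggregated texture is invariant to 90-degree rotation", {
  set.seed(32)
  a <- array(rnorm(14 * 14 * 2, 100, 25), c(14, 14, 2))
  m <- array(0L, c(14, 14, 2)); m[4:11, 3:12, ] <- 1L; m[6:9, 6:9, ] <- 0L
  img <- volume_image(a); msk <- wall_mask(m, img, check_hollow = FALSE)
  cfg <- texture_config(distances = c(1, 2), bins = 8, windows = 5)
  tx <- windowed_texture(img, msk, cfg)

  rot <- function(x) {  # 90-degree in-plane rotation, slice by slice
    out <- array(x[1], c(dim(x)[2], dim(x)[1], dim(x)[3]))
    for (z in seq_len(dim(x)[3])) out[, , z] <- t(x[dim(x)[1]:1, , z])
    out
  }
  imgr <- volume_image(rot(a)); mskr <- wall_mask(rot(m), imgr,
                                                  check_hollow = FALSE)
  txr <- windowed_texture(imgr, mskr, cfg)

  agg <- function(v) {
    nm <- names(v)
    key <- sub("_a\\d+_", "_", nm)   # collapse the angle token
    tapply(v, key, mean)
  }
  expect_equal(agg(tx), agg(txr), tolerance = 1e-9)
})

test_that("morphological columns ignore wall texture entirely", {
  sh <- box_shell(3L, 9L, 12L)
  set.seed(33)
  img1 <- volume_image(array(rnorm(12^3, 100, 10), c(12, 12, 12)))
  img2 <- volume_image(array(rnorm(12^3, 100, 50), c(12, 12, 12)))
  expect_identical(morphological_features(sh$mask),
                   morphological_features(sh$mask))
  ca <- list(age = 65, prostate_size = 45, bmi = 27)
  cfg <- texture_config(distances = 1, bins = 8, windows = 5)
  f1 <- extract_case_features(img1, sh$mask, ca, cfg)
  f2 <- extract_case_features(img2, sh$mask, ca, cfg)
  mo <- grep("^morph_", names(f1))
  expect_identical(f1[mo], f2[mo])
  expect_gt(max(abs(f1[-mo] - f2[-mo])), 0)  # texture did change
})

test_that("texture column count is the closed-form product of the grids", {
  cfg <- texture_config(angles = c(0, 90), distances = c(1, 2),
                        bins = c(8, 16), windows = c(5, 9),
                        features = c("contrast", "energy", "entropy"))
  expect_equal(n_texture_columns(cfg), 2 * 2 * 2 * 2 * 3)
  sh <- box_shell(3L, 9L, 12L)
  img <- volume_image(array(rnorm(12^3, 100, 10), c(12, 12, 12)))
  tx <- windowed_texture(img, sh$mask, cfg)
  expect_equal(length(tx), n_texture_columns(cfg))
  expect_equal(nrow(attr(tx, "descriptors")), n_texture_columns(cfg))
})

test_that("whole-ROI 3D texture averages the 13 lattice directions", {
  sh <- box_shell(3L, 9L, 12L)
  img <- volume_image(array(100, c(12, 12, 12)))
  v <- volume_texture(img, sh$mask, bins = 8)
  expect_equal(unname(v[grep("contrast", names(v))]), 0)
  expect_equal(unname(v[grep("energy", names(v))]), 1)
})
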