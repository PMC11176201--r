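test_that("quantization uses equal-width bins over the requested range", {
  expect_equal(quantize(c(0, 1, 2, 3), 4, range = c(0, 3)), c(0L, 1L, 2L, 3L))
  expect_equal(quantize(rep(5, 10), 8, range = c(5, 5)), rep(0L, 10))
  # closed-form equal-width edges: 0..99 into 8 bins of width 12.375
  x <- 0:99
  lev <- quantize(x, 8, range = c(0, 99))
  expect_equal(lev, pmin(floor(x / 12.375), 7))
  # robust policy clips, never drops
  y <- c(rep(10, 98), -1e6, 1e6)
  lev2 <- quantize(y, 4)
  expect_true(all(lev2 >= 0 & lev2 <= 3))
})

test_that("glcm reproduces the worked 3x3 co-occurrence example", {
  img <- t(matrix(c(0, 0, 1,
                    0, 0, 1,
                    0, 2, 2), 3, 3, byrow = TRUE))  # axis 1 = within-row step
  g <- glcm(img, nbins = 3, angle = 0, distance = 1, symmetric = TRUE,
            normalize = TRUE)
  expect_equal(g[1, 1], 4 / 12)
  expect_equal(g[1, 2], 2 / 12); expect_equal(g[2, 1], 2 / 12)
  expect_equal(g[1, 3], 1 / 12); expect_equal(g[3, 1], 1 / 12)
  expect_equal(g[3, 3], 2 / 12)
  expect_equal(sum(g), 1)
  h <- haralick(g, c("contrast", "energy"))
  expect_equal(unname(h["contrast"]), 1.0)
  expect_equal(unname(h["energy"]), 30 / 144)
})

test_that("glcm counts equal the brute-force pair oracle on random arrays", {
  set.seed(11)
  angles2 <- c(0, 45, 90, 135)
  for (rep in 1:60) {
    d <- c(sample(3:8, 1), sample(3:8, 1), sample(1:3, 1))
    b <- sample(2:5, 1)
    lev <- array(sample(0:(b - 1), prod(d), replace = TRUE), d)
    msk <- array(sample(0:1, prod(d), TRUE, prob = c(0.25, 0.75)), d)
    if (d[3] == 1L) {
      a <- sample(angles2, 1); dist <- sample(1:2, 1)
      off <- c(wallradiomics:::glcm_offset(a, 2L) * dist, 0L)
      g <- glcm(lev[, , 1], msk[, , 1], angle = a, distance = dist,
                nbins = b, normalize = FALSE)
      o <- glcm_oracle(lev, msk, off, b, normalize = FALSE)
    } else {
      a <- sample(1:13, 1); dist <- sample(1:2, 1)
      off <- wallradiomics:::glcm_offset(a, 3L) * dist
      g <- glcm(lev, msk, angle = a, distance = dist, nbins = b,
                normalize = FALSE)
      o <- glcm_oracle(lev, msk, off, b, normalize = FALSE)
    }
    expect_identical(as.vector(g), as.vector(o))
    expect_identical(dim(g), dim(o))
  }
})

test_that("degenerate images give the expected co-occurrence structure", {
  const <- matrix(1L, 4, 4)
  g <- glcm(const, nbins = 3, angle = 0, distance = 1)
  expect_equal(g[2, 2], 1)          # single diagonal entry
  expect_equal(sum(g), 1)
  h <- haralick(g)
  expect_equal(unname(h["contrast"]), 0)
  expect_equal(unname(h["energy"]), 1)
  expect_equal(unname(h["entropy"]), 0)
  expect_equal(unname(h["correlation"]), 0)  # zero marginal SD convention

  # checkerboard at d=1 horizontal: maximal contrast for b=2
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  g2 <- glcm(cb, nbins = 2, angle = 0, distance = 1)
  expect_equal(unname(haralick(g2, "contrast")), 1.0)
  off <- c(1L, 0L)
  expect_equal(unname(haralick(g2, "energy")),
               sum(glcm_oracle(array(cb, c(6, 6, 1)),
                               array(1, c(6, 6, 1)), c(off, 0L), 2)^2))

  # symmetric flag produces a symmetric matrix by construction
  set.seed(2)
  r <- matrix(sample(0:3, 36, TRUE), 6, 6)
  gs <- glcm(r, nbins = 4, angle = 45, distance = 1, symmetric = TRUE)
  expect_equal(gs, t(gs))

  # no valid pairs: flagged empty, features are NaN sentinels
  ge <- glcm(matrix(0L, 2, 2), matrix(0, 2, 2), nbins = 2)
  expect_true(attr(ge, "empty"))
  expect_true(all(is.nan(haralick(ge))))
})

test_that("haralick features match the independent pair-list computation", {
  set.seed(21)
  for (rep in 1:40) {
    d <- c(sample(4:8, 1), sample(4:8, 1))
    b <- sample(3:6, 1)
    lev <- matrix(sample(0:(b - 1), prod(d), TRUE), d[1], d[2])
    msk <- matrix(sample(0:1, prod(d), TRUE, prob = c(0.2, 0.8)), d[1], d[2])
    a <- sample(c(0, 45, 90, 135), 1)
    off <- c(wallradiomics:::glcm_offset(a, 2L), 0L)
    oracle <- haralick_pair_oracle(array(lev, c(d, 1)), array(msk, c(d, 1)),
                                   off, b)
    if (is.null(oracle)) next
    g <- glcm(lev, msk, angle = a, distance = 1, nbins = b)
    mine <- haralick(g)
    expect_equal(unname(mine), unname(oracle[names(mine)]), tolerance = 1e-10)
  }
})
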