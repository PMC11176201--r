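test_that("cohort generation is a pure function of config and seed", {
  cfg <- synthetic_config(n_negative = 2L, n_positive = 2L, seed = 9L,
                          grid_shape = c(24L, 24L, 20L),
                          outer_radii_mm = c(7, 9),
                          wall_thickness_mm = c(3, 4.5))
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  generate_cohort(cfg, d1)
  generate_cohort(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  cfg2 <- cfg; cfg2$seed <- 10L
  generate_cohort(cfg2, d3)
  v1 <- read_volume(file.path(d1, "case001_img.nii"))
  v3 <- read_volume(file.path(d3, "case001_img.nii"))
  expect_gt(max(abs(v1$data - v3$data)), 0)
  # config echo present in both manifest headers
  h1 <- readLines(file.path(d1, "manifest.csv"), n = 12)
  h3 <- readLines(file.path(d3, "manifest.csv"), n = 12)
  expect_true(any(grepl("^#texture_effect", h1)))
  expect_identical(grep("^#n_negative", h1, value = TRUE),
                   grep("^#n_negative", h3, value = TRUE))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("cases respect class structure: IPSS ranges and hollow masks", {
  cfg <- synthetic_config(n_negative = 3L, n_positive = 3L, seed = 5L,
                          grid_shape = c(24L, 24L, 20L),
                          outer_radii_mm = c(7, 9),
                          wall_thickness_mm = c(3, 4.5))
  d <- tempfile()
  generate_cohort(cfg, d)
  man <- load_manifest(file.path(d, "manifest.csv"), quiet = TRUE)
  expect_equal(man$label, ipss_to_label(man$ipss))
  expect_true(all(man$ipss[man$label == "negative"] <= 7))
  expect_true(all(man$ipss[man$label == "positive"] >= 8))
  for (i in seq_len(nrow(man))) {
    img <- read_volume(man$image[i])
    expect_s3_class(read_mask(man$mask[i], img), "wall_mask")  # hollow
  }
  unlink(d, recursive = TRUE)
})

test_that("the generated wall respects the configured thickness", {
  # 4 mm walls at 1 mm spacing: distance-transform thickness within 4 +- 1
  cfg <- synthetic_config(n_negative = 3L, n_positive = 1L, seed = 3L,
                          wall_thickness_mm = c(4, 4))
  d <- tempfile()
  generate_cohort(cfg, d)
  man <- load_manifest(file.path(d, "manifest.csv"), quiet = TRUE)
  for (i in 1:3) {
    img <- read_volume(man$image[i])
    msk <- read_mask(man$mask[i], img)
    mo <- morphological_features(msk)
    expect_gt(mo[["morph_thickness_mean"]], 3)
    expect_lt(mo[["morph_thickness_mean"]], 5)
  }
  unlink(d, recursive = TRUE)
})

test_that("class proportions follow the configured imbalance", {
  cfg <- synthetic_config(n_negative = 50L, n_positive = 37L)
  labels <- rep(c("negative", "positive"),
                c(cfg$n_negative, cfg$n_positive))
  expect_equal(length(labels), 87L)
  expect_equal(floor(100 * mean(labels == "negative")), 57)
  expect_equal(floor(100 * mean(labels == "positive")), 42)
})

test_that("impossible wall thickness is rejected", {
  expect_error(synthetic_config(wall_thickness_mm = c(1, 2)),
               "at least 2 voxels")
})

test_that("downstream separability is monotone in the texture effect", {
  # mean CV AUC over 5 seeds at no / moderate / strong texture contrast;
  # small slack absorbs CV noise at this cohort size
  txc <- texture_config(angles = c(0, 45, 90, 135), distances = 1,
                        bins = 8, windows = 5)
  mean_auc <- function(effect) {
    aucs <- vapply(1:5, function(s) {
      cfg <- synthetic_config(n_negative = 12L, n_positive = 8L,
                              grid_shape = c(26L, 26L, 20L),
                              outer_radii_mm = c(7.5, 10),
                              wall_thickness_mm = c(3, 5),
                              texture_effect = effect,
                              clinical_model = flat_clinical(),
                              seed = 400L + s)
      d <- tempfile()
      generate_cohort(cfg, d)
      man <- load_manifest(file.path(d, "manifest.csv"), quiet = TRUE)
      tab <- extract_features(man, txc, quiet = TRUE)
      unlink(d, recursive = TRUE)
      tx <- tab$descriptors$name[tab$descriptors$category == "texture"]
      repeated_cv(tab, man$label, tx, k = 4L, repeats = 5L,
                  seed = 500L + s)$mean$auc
    }, numeric(1))
    mean(aucs)
  }
  auc0 <- mean_auc(0); auc1 <- mean_auc(0.6); auc2 <- mean_auc(1.5)
  expect_lte(auc0, auc1 + 0.05)
  expect_lte(auc1, auc2 + 0.05)
  expect_gt(auc2, auc0 + 0.2)   # strong contrast clearly separates
  expect_gt(auc2, 0.9)
})
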