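#' Configuration for the synthetic phantom cohort
#'
#' Defines the statistical structure of a phantom cohort of hollow
#' ellipsoidal "bladder walls". The two classes are matched in wall
#' morphology and global intensity by default; they differ in wall texture
#' (correlation length of a stationary random field, controlled by
#' `texture_effect`) and in the prostate-size clinical covariate. This
#' mirrors the structure the analysis assumes: texture carries the class
#' signal, thickness and intensity do not, and among the clinical variables
#' only prostate size separates the classes.
#'
#' @param n_negative,n_positive class sizes (defaults 50 and 37, a 57/43
#'   imbalance).
#' @param grid_shape integer length-3 voxel grid.
#' @param spacing voxel spacing in mm.
#' @param outer_radii_mm range from which each outer semi-axis is drawn.
#' @param wall_thickness_mm range of wall thickness, mm (must discretize to
#'   at least 2 voxels).
#' @param texture_effect added texture correlation length (mm) in the
#'   positive class; 0 makes the classes exchangeable in texture.
#' @param intensity_effect added mean wall intensity in the positive class
#'   (default 0: intensity features carry no signal).
#' @param morphology_effect added wall thickness (mm) in the positive class
#'   (default 0: thickness features carry no signal).
#' @param clinical_model per-variable list of class means/SDs, in order
#'   (negative, positive). By default age and BMI are identically
#'   distributed and prostate size is larger in the positive class.
#' @param base_intensity named list of background / cavity / wall mean
#'   intensities (arbitrary MR-like units; cavity bright as on T2).
#' @param wall_texture_sd marginal SD of the wall texture field.
#' @param texture_corr_mm baseline texture correlation length, mm.
#' @param noise_sd additive white noise SD, whole volume.
#' @param seed master seed; per-case seeds are derived from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_negative = 50L, n_positive = 37L,
                             grid_shape = c(36L, 36L, 28L),
                             spacing = c(1, 1, 1),
                             outer_radii_mm = c(9, 13),
                             wall_thickness_mm = c(3.5, 6),
                             texture_effect = 1.2,
                             intensity_effect = 0,
                             morphology_effect = 0,
                             clinical_model = list(
                               age = list(mean = c(64, 64), sd = c(8, 8)),
                               bmi = list(mean = c(27, 27), sd = c(4, 4)),
                               prostate_size = list(mean = c(38, 55),
                                                    sd = c(13, 13))),
                             base_intensity = list(background = 60,
                                                   cavity = 330, wall = 170),
                             wall_texture_sd = 35,
                             texture_corr_mm = 0.8,
                             noise_sd = 8,
                             seed = 1L) {
  stopifnot(n_negative >= 1, n_positive >= 1,
            length(grid_shape) == 3, all(grid_shape >= 8),
            all(spacing > 0), diff(outer_radii_mm) >= 0,
            diff(wall_thickness_mm) >= 0,
            texture_effect >= 0, morphology_effect >= 0,
            wall_texture_sd >= 0, noise_sd >= 0)
  if (wall_thickness_mm[1] < 2 * max(spacing))
    stop("wall thickness range must be at least 2 voxels at this spacing")
  structure(as.list(environment()), class = "synthetic_config")
}

# Separable Gaussian smoothing with edge renormalization; sigma in voxels,
# one value per axis.
gaussian_smooth3 <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 1e-8) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-((-r:r)^2) / (2 * s^2))
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    d <- dim(a)
    m <- matrix(a, nrow = d[1])
    n <- d[1]
    num <- matrix(0, n, ncol(m)); den <- numeric(n)
    for (k in -r:r) {
      src <- seq_len(n) + k
      ok <- src >= 1L & src <= n
      num[ok, ] <- num[ok, ] + w[k + r + 1] * m[src[ok], , drop = FALSE]
      den[ok] <- den[ok] + w[k + r + 1]
    }
    arr <- aperm(array(num / den, d), order(perm))
  }
  arr
}

# Ellipsoid indicator on the voxel grid; centre in mm, semi-axes in mm.
ellipsoid_mask <- function(grid_shape, spacing, centre, semi) {
  cx <- (seq_len(grid_shape[1]) - 1) * spacing[1]
  cy <- (seq_len(grid_shape[2]) - 1) * spacing[2]
  cz <- (seq_len(grid_shape[3]) - 1) * spacing[3]
  dx2 <- ((cx - centre[1]) / semi[1])^2
  dy2 <- ((cy - centre[2]) / semi[2])^2
  dz2 <- ((cz - centre[3]) / semi[3])^2
  q <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  array(q <= 1, grid_shape)
}

#' Generate one synthetic case
#'
#' Builds a hollow ellipsoidal wall (outer ellipsoid minus an inner
#' ellipsoid offset by the sampled wall thickness), fills the wall with a
#' stationary correlated Gaussian texture field whose correlation length
#' depends on the class, samples clinical variables and an IPSS consistent
#' with the class, and writes the volume and mask as NIfTI.
#'
#' @param config a [synthetic_config()].
#' @param class_label `"negative"` or `"positive"`.
#' @param case_seed integer seed for this case.
#' @param dir output directory for the NIfTI files.
#' @param case_id identifier used in file names.
#' @return A one-row data frame: the manifest record for this case.
#' @export
generate_case <- function(config, class_label, case_seed, dir, case_id) {
  stopifnot(class_label %in% c("negative", "positive"))
  cls <- if (class_label == "positive") 2L else 1L
  with_seed(case_seed, generate_case_impl(config, cls, dir, case_id))
}

generate_case_impl <- function(config, cls, dir, case_id) {
  gs <- config$grid_shape; sp <- config$spacing
  fov <- (gs - 1) * sp

  mask_data <- NULL
  for (try in 1:100) {
    semi <- runif(3, config$outer_radii_mm[1], config$outer_radii_mm[2])
    thick <- runif(1, config$wall_thickness_mm[1], config$wall_thickness_mm[2]) +
      (cls == 2L) * config$morphology_effect
    centre <- fov / 2 + runif(3, -1, 1)
    if (thick < 2 * max(sp) || any(semi - thick < 2 * max(sp))) next
    outer_m <- ellipsoid_mask(gs, sp, centre, semi)
    inner_m <- ellipsoid_mask(gs, sp, centre, semi - thick)
    m <- array(as.integer(outer_m & !inner_m), gs)
    if (sum(inner_m) > 0 && sum(m) > 0 && has_enclosed_cavity(m)) {
      mask_data <- m
      break
    }
  }
  if (is.null(mask_data))
    stop("could not realize a hollow wall >= 2 voxels thick in 100 tries")

  # texture field: white noise smoothed to a class-dependent correlation
  # length, then rescaled to the configured marginal SD over wall voxels
  corr_mm <- config$texture_corr_mm + (cls == 2L) * config$texture_effect
  field <- array(rnorm(prod(gs)), gs)
  field <- gaussian_smooth3(field, corr_mm / sp)
  wall_idx <- mask_data == 1L
  f_sd <- sd(field[wall_idx])
  if (f_sd > 0) field <- (field - mean(field[wall_idx])) / f_sd
  wall_mean <- config$base_intensity$wall + (cls == 2L) * config$intensity_effect

  vol <- array(config$base_intensity$background, gs)
  vol[inner_m] <- config$base_intensity$cavity
  vol[wall_idx] <- wall_mean + config$wall_texture_sd * field[wall_idx]
  vol <- vol + rnorm(prod(gs), sd = config$noise_sd)

  img <- volume_image(vol, sp)
  msk <- wall_mask(mask_data, img)
  img_path <- file.path(dir, paste0(case_id, "_img.nii"))
  msk_path <- file.path(dir, paste0(case_id, "_mask.nii"))
  write_volume(img, img_path)
  write_volume(msk, msk_path)

  rclin <- function(v) {
    p <- config$clinical_model[[v]]
    for (i in 1:50) {
      x <- rnorm(1, p$mean[cls], p$sd[cls])
      if (x > 0) return(x)
    }
    abs(x) + 1e-3
  }
  ipss <- if (cls == 2L) sample(8:35, 1) else sample(0:7, 1)
  data.frame(case_id = case_id,
             image = basename(img_path), mask = basename(msk_path),
             age = rclin("age"), bmi = rclin("bmi"),
             prostate_size = rclin("prostate_size"),
             ipss = ipss, stringsAsFactors = FALSE)
}

#' Generate a full phantom cohort
#'
#' Writes `n_negative + n_positive` cases and a manifest CSV whose comment
#' header echoes the configuration. Per-case seeds are drawn once from the
#' master seed, so the cohort is a pure function of `(config, seed)` and
#' each case can be regenerated independently.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return Path of the written manifest CSV, invisibly; the loaded manifest
#'   data frame as attribute is not kept — use [load_manifest()].
#' @export
generate_cohort <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- config$n_negative + config$n_positive
  case_seeds <- with_seed(config$seed,
                          sample.int(.Machine$integer.max - 1L, n))
  labels <- rep(c("negative", "positive"),
                c(config$n_negative, config$n_positive))
  ids <- sprintf("case%03d", seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n))
    rows[[i]] <- generate_case(config, labels[i], case_seeds[i], dir, ids[i])
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  echo <- config[c("n_negative", "n_positive", "texture_effect",
                   "intensity_effect", "morphology_effect", "noise_sd",
                   "wall_texture_sd", "texture_corr_mm", "seed")]
  hdr <- c("#wallradiomics synthetic cohort",
           paste0("#", names(echo), ": ",
                  vapply(echo, function(x) paste(format(x), collapse = ","),
                         "")),
           paste0("#grid_shape: ", paste(config$grid_shape, collapse = "x")),
           paste0("#spacing: ", paste(format(config$spacing), collapse = "x")))
  writeLines(hdr, path)
  suppressWarnings(write.table(manifest, path, sep = ",", row.names = FALSE,
                               col.names = TRUE, quote = FALSE,
                               append = TRUE))
  invisible(path)
}
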