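#' Texture sweep configuration
#'
#' Defines the grid of co-occurrence parameters swept by
#' [windowed_texture()]: angles `a`, distances `d` (voxels), gray-level
#' counts `b`, window sizes `w` (odd, in-plane voxels) and Haralick
#' features `f`. One feature column is produced per (f, a, d, b, w)
#' combination, named `f_a{a}_d{d}_b{b}_w{w}`.
#'
#' @param angles in-plane co-occurrence angles, degrees (subset of
#'   0/45/90/135).
#' @param distances offset lengths in voxels.
#' @param bins gray-level counts.
#' @param windows odd window sizes, `>= 3`.
#' @param features Haralick feature names (see [haralick_features()]).
#' @param min_mask_fraction minimum in-mask fraction of a window for it to
#'   contribute (out-of-grid voxels count as background).
#' @param aggregate statistic pooling windows; only `"mean"` is provided.
#' @param range_policy quantization range policy, see [quantize()].
#' @return A list of class `texture_config`.
#' @export
texture_config <- function(angles = c(0, 45, 90, 135),
                           distances = c(1, 2, 4),
                           bins = c(8, 16, 32),
                           windows = c(5, 9, 15),
                           features = haralick_features(),
                           min_mask_fraction = 0.5,
                           aggregate = "mean",
                           range_policy = "robust") {
  stopifnot(length(angles) >= 1, all(angles %in% c(0, 45, 90, 135)),
            all(distances >= 1), all(bins >= 2),
            all(windows >= 3), all(windows %% 2 == 1),
            length(features) >= 1,
            min_mask_fraction > 0, min_mask_fraction <= 1,
            aggregate == "mean")
  features <- match.arg(features, haralick_features(), several.ok = TRUE)
  structure(list(angles = angles, distances = distances, bins = bins,
                 windows = windows, features = features,
                 min_mask_fraction = min_mask_fraction,
                 aggregate = aggregate, range_policy = range_policy),
            class = "texture_config")
}

#' Number of texture columns a config produces
#' @param cfg a [texture_config()].
#' @return Integer column count (pure function of the grids).
#' @export
n_texture_columns <- function(cfg) {
  length(cfg$angles) * length(cfg$distances) * length(cfg$bins) *
    length(cfg$windows) * length(cfg$features)
}

#' Windowed GLCM texture features over the wall ROI
#'
#' For every parameter combination, a `w x w` window slides in-plane over
#' each slice; windows with at least `min_mask_fraction` in-mask voxels
#' contribute one GLCM (pairs with both endpoints in window and mask) and
#' its Haralick features, and windows are pooled by the mean. Quantization
#' is per-volume over the robust in-mask range so all windows share gray
#' levels. Combinations with no qualifying window yield `NaN` sentinels,
#' resolved at table assembly.
#'
#' @param image a standardized [volume_image()].
#' @param mask the paired [wall_mask()].
#' @param cfg a [texture_config()].
#' @return Named numeric vector of texture features, with a `descriptors`
#'   attribute (data frame of per-column parameters).
#' @export
windowed_texture <- function(image, mask, cfg = texture_config()) {
  stopifnot(inherits(image, "volume_image"), inherits(mask, "wall_mask"))
  nz <- image$shape[3]
  offs <- expand.grid(angle = cfg$angles, distance = cfg$distances)
  dirs <- vapply(offs$angle, glcm_offset, integer(2), ndim = 2L)
  offx <- as.integer(dirs[1, ] * offs$distance)
  offy <- as.integer(dirs[2, ] * offs$distance)
  feat_idx <- match(cfg$features, haralick_features())

  vals <- numeric(0); desc <- list()
  for (b in cfg$bins) {
    lev <- quantize(image$data, b, mask = mask$data,
                    range_policy = cfg$range_policy)
    for (w in cfg$windows) {
      sums <- matrix(0, length(offx), 10)
      counts <- integer(length(offx))
      for (z in seq_len(nz)) {
        mz <- mask$data[, , z]
        if (!any(mz != 0L)) next
        res <- glcm_window_slice_cpp(lev[, , z], mz, offx, offy,
                                     as.integer(b), as.integer(w),
                                     cfg$min_mask_fraction)
        sums <- sums + res$sums
        counts <- counts + res$counts
      }
      means <- sums / ifelse(counts > 0, counts, NA)  # NaN/NA sentinel
      for (o in seq_len(nrow(offs))) {
        v <- means[o, feat_idx]
        nm <- sprintf("%s_a%d_d%d_b%d_w%d", cfg$features, offs$angle[o],
                      offs$distance[o], b, w)
        vals <- c(vals, structure(as.numeric(v), names = nm))
        desc[[length(desc) + 1]] <-
          data.frame(name = nm, category = "texture",
                     feature = cfg$features,
                     angle = as.integer(offs$angle[o]),
                     distance = as.integer(offs$distance[o]),
                     bins = as.integer(b), window = as.integer(w),
                     stringsAsFactors = FALSE)
      }
    }
  }
  structure(vals, descriptors = do.call(rbind, desc))
}

#' Whole-ROI 3D co-occurrence features
#'
#' Complement to the windowed in-plane sweep: a single GLCM per direction
#' over the full 3D ROI, averaged over the 13 unique lattice directions.
#' Useful when slices are thin enough that through-plane offsets are
#' isotropic in tissue terms.
#'
#' @inheritParams windowed_texture
#' @param bins gray-level count.
#' @param distance offset length in voxels.
#' @return Named numeric vector, one value per Haralick feature.
#' @export
volume_texture <- function(image, mask, bins = 16, distance = 1) {
  lev <- quantize(image$data, bins, mask = mask$data)
  acc <- matrix(NA_real_, 13, length(haralick_features()))
  for (a in 1:13) {
    p <- glcm(lev, mask$data, angle = a, distance = distance, nbins = bins)
    if (!isTRUE(attr(p, "empty"))) acc[a, ] <- haralick(p)
  }
  out <- colMeans(acc, na.rm = TRUE)
  names(out) <- sprintf("%s_3d_d%d_b%d", haralick_features(), distance, bins)
  out
}
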