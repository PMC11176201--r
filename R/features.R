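#' Morphological features of a hollow wall mask
#'
#' Shell morphometry in physical units: wall volume (voxel count times
#' voxel volume), wall surface area by face counting (exposed voxel faces,
#' a documented overestimate of a smooth surface), local wall thickness
#' statistics from twice the Euclidean distance transform sampled on the
#' medial surface (distance-ridge voxels), sphericity of the outer surface,
#' equivalent-sphere diameters of the outer region and the cavity, and
#' bounding-box extents.
#'
#' @param mask a [wall_mask()].
#' @return Named numeric vector with a `descriptors` attribute.
#' @export
morphological_features <- function(mask) {
  sp <- mask$spacing
  m <- mask$data
  voxvol <- prod(sp)
  wall_volume <- sum(m) * voxvol

  # outer region = wall plus enclosed cavities (everything not reachable
  # from the border through background)
  outside <- border_connected_background(m)
  outer <- !outside
  cavity <- outer & (m == 0L)
  outer_volume <- sum(outer) * voxvol
  cavity_volume <- sum(cavity) * voxvol

  face_area <- function(region) {
    d <- dim(region)
    a <- 0
    pad_diff <- function(ax) {
      r <- aperm(region, c(ax, setdiff(1:3, ax)))
      dd <- dim(r)
      grown <- array(FALSE, dd + c(2L, 0L, 0L))
      grown[2:(dd[1] + 1L), , ] <- r
      sum(grown[-nrow(grown), , ] != grown[-1, , ])
    }
    areas <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
    for (ax in 1:3) a <- a + pad_diff(ax) * areas[ax]
    a
  }
  wall_area <- face_area(m == 1L)
  outer_area <- face_area(outer)
  sphericity <- pi^(1 / 3) * (6 * outer_volume)^(2 / 3) / outer_area

  # local thickness: 2 x distance-to-background on the distance ridge
  dist2 <- edt3_cpp(as.integer(m), dim(m), sp)
  dist <- array(sqrt(dist2), dim(m))
  ridge <- local_maxima6(dist) & (m == 1L)
  th <- 2 * dist[ridge]
  if (!length(th)) th <- 2 * max(dist)

  ext <- apply(which(m == 1L, arr.ind = TRUE), 2, range)
  bbox <- (ext[2, ] - ext[1, ] + 1) * sp

  vals <- c(wall_volume = wall_volume,
            wall_surface_area = wall_area,
            thickness_mean = mean(th),
            thickness_median = median(th),
            thickness_max = max(th),
            thickness_sd = if (length(th) > 1) sd(th) else 0,
            sphericity = sphericity,
            outer_diameter = (6 * outer_volume / pi)^(1 / 3),
            cavity_diameter = (6 * cavity_volume / pi)^(1 / 3),
            bbox_x = bbox[[1]], bbox_y = bbox[[2]], bbox_z = bbox[[3]])
  names(vals) <- paste0("morph_", names(vals))
  structure(vals, descriptors = plain_descriptors(names(vals), "morphological"))
}

# voxels whose value is >= all 6-neighbours (ties allowed)
local_maxima6 <- function(a) {
  d <- dim(a)
  ge <- array(TRUE, d)
  cmp <- function(keep, nb_keep) {
    # keep / nb_keep: index lists along each axis
    ge[keep[[1]], keep[[2]], keep[[3]]] <<-
      ge[keep[[1]], keep[[2]], keep[[3]], drop = FALSE] &
      (a[keep[[1]], keep[[2]], keep[[3]], drop = FALSE] >=
         a[nb_keep[[1]], nb_keep[[2]], nb_keep[[3]], drop = FALSE])
  }
  full <- lapply(d, seq_len)
  for (ax in 1:3) {
    lo <- full; lo[[ax]] <- 1:(d[ax] - 1)
    hi <- full; hi[[ax]] <- 2:d[ax]
    cmp(lo, hi)
    cmp(hi, lo)
  }
  ge
}

plain_descriptors <- function(names, category) {
  data.frame(name = names, category = category, feature = NA_character_,
             angle = NA_integer_, distance = NA_integer_,
             bins = NA_integer_, window = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Intensity features over the wall ROI
#'
#' First-order statistics of in-mask intensities: location, spread, order
#' statistics, skewness, kurtosis (non-excess, `m4 / m2^2`), and histogram
#' entropy in bits over `hist_bins` equal bins spanning `standard_range`.
#'
#' @param image a standardized [volume_image()].
#' @param mask the paired [wall_mask()].
#' @param standard_range intensity range for the entropy histogram
#'   (defaults to the standardization range 0..4095).
#' @param hist_bins number of histogram bins (default 64).
#' @return Named numeric vector with a `descriptors` attribute.
#' @export
intensity_features <- function(image, mask, standard_range = c(0, 4095),
                               hist_bins = 64L) {
  v <- image$data[mask$data == 1L]
  q <- quantile(v, c(0.05, 0.25, 0.75, 0.95), names = FALSE)
  m <- mean(v); s <- sd(v)
  ctr <- v - m
  skew <- if (s > 0) mean(ctr^3) / s^3 else 0
  kurt <- if (s > 0) mean(ctr^4) / mean(ctr^2)^2 else 0
  lev <- quantize(v, hist_bins, range = standard_range)
  p <- tabulate(lev + 1L, hist_bins) / length(lev)
  p <- p[p > 0]
  vals <- c(mean = m, median = median(v), sd = s, min = min(v), max = max(v),
            p5 = q[1], p25 = q[2], p75 = q[3], p95 = q[4],
            skewness = skew, kurtosis = kurt,
            hist_entropy = -sum(p * log2(p)))
  names(vals) <- paste0("int_", names(vals))
  structure(vals, descriptors = plain_descriptors(names(vals), "intensity"))
}

#' Clinical covariate passthrough
#'
#' @param case one manifest row (or any list) with `age`, `prostate_size`
#'   and `bmi`.
#' @return Named numeric vector with a `descriptors` attribute; column
#'   order is fixed (age, prostate_size, bmi).
#' @export
clinical_features <- function(case) {
  vals <- c(clin_age = as.numeric(case$age),
            clin_prostate_size = as.numeric(case$prostate_size),
            clin_bmi = as.numeric(case$bmi))
  if (any(!is.finite(vals))) stop("incomplete clinical record")
  structure(vals, descriptors = plain_descriptors(names(vals), "clinical"))
}

#' Extract all feature families for one case
#'
#' @param image standardized [volume_image()]; @param mask paired mask.
#' @param case manifest row with clinical variables.
#' @param cfg a [texture_config()].
#' @param standard_range intensity range for histogram entropy.
#' @return Named numeric vector (category order: morphological, intensity,
#'   texture, clinical) with `descriptors` attribute.
#' @export
extract_case_features <- function(image, mask, case, cfg = texture_config(),
                                  standard_range = c(0, 4095)) {
  parts <- list(morphological_features(mask),
                intensity_features(image, mask, standard_range),
                windowed_texture(image, mask, cfg),
                clinical_features(case))
  vals <- do.call(c, lapply(parts, as.numeric))
  names(vals) <- unlist(lapply(parts, names))
  structure(vals,
            descriptors = do.call(rbind, lapply(parts, attr, "descriptors")))
}

#' Assemble per-case feature vectors into a feature table
#'
#' Rows are bound in case order; sentinel (non-finite) values are imputed
#' by the column median over finite entries, one log line per affected
#' column; columns with more than half sentinels are dropped with a
#' warning. The result satisfies the feature-table invariants (no
#' non-finite entries, unique descriptors).
#'
#' @param rows list of per-case feature vectors from
#'   [extract_case_features()] (identical layouts).
#' @param case_ids character vector of case identifiers.
#' @param quiet suppress imputation log lines.
#' @return A [feature_table()] with attribute `n_imputed`.
#' @export
assemble_feature_table <- function(rows, case_ids, quiet = FALSE) {
  stopifnot(length(rows) == length(case_ids), length(rows) >= 1)
  desc <- attr(rows[[1]], "descriptors")
  mat <- do.call(rbind, lapply(rows, as.numeric))
  colnames(mat) <- desc$name
  bad <- !is.finite(mat)
  frac <- colMeans(bad)
  drop <- frac > 0.5
  if (any(drop)) {
    warning(sum(drop), " feature column(s) dropped: > 50% sentinel values (",
            paste(head(desc$name[drop], 5), collapse = ", "),
            if (sum(drop) > 5) ", ..." else "", ")")
    mat <- mat[, !drop, drop = FALSE]
    desc <- desc[!drop, , drop = FALSE]
    bad <- bad[, !drop, drop = FALSE]
  }
  n_imputed <- 0L
  for (jj in which(colSums(bad) > 0)) {
    med <- median(mat[!bad[, jj], jj])
    mat[bad[, jj], jj] <- med
    n_imputed <- n_imputed + sum(bad[, jj])
    if (!quiet)
      message(sprintf("imputed %d sentinel(s) in %s by column median",
                      sum(bad[, jj]), desc$name[jj]))
  }
  structure(feature_table(mat, desc, case_ids), n_imputed = n_imputed)
}

#' Extract a feature table for a whole cohort
#'
#' Convenience driver: for each manifest row, read volume and mask, crop to
#' the ROI with a margin, optionally standardize intensities, extract all
#' families and assemble the table.
#'
#' @param manifest data frame from [load_manifest()].
#' @param cfg a [texture_config()].
#' @param standardizer optional `standardization_model`; when given, each
#'   cropped volume is standardized before feature extraction.
#' @param margin_vox crop margin in voxels (default 8, enough context for
#'   the largest default window).
#' @param quiet passed to [assemble_feature_table()].
#' @return A [feature_table()].
#' @export
extract_features <- function(manifest, cfg = texture_config(),
                             standardizer = NULL, margin_vox = 8L,
                             quiet = FALSE) {
  rows <- vector("list", nrow(manifest))
  rng <- if (is.null(standardizer)) c(0, 4095)
         else c(standardizer$config$s_min, standardizer$config$s_max)
  for (i in seq_len(nrow(manifest))) {
    img <- read_volume(manifest$image[i])
    msk <- read_mask(manifest$mask[i], img)
    roi <- crop_to_mask(img, msk, margin_vox)
    if (!is.null(standardizer))
      roi$image <- apply_standardizer(standardizer, roi$image)
    rows[[i]] <- extract_case_features(roi$image, roi$mask, manifest[i, ],
                                       cfg, rng)
  }
  assemble_feature_table(rows, manifest$case_id, quiet = quiet)
}
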