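#' Histogram-landmark intensity standardization
#'
#' MR intensities are not in standard units: the same tissue maps to
#' different gray levels in different acquisitions. The landmark method of
#' Nyul-type standardization fixes this in two phases. Training maps each
#' image's intensity landmarks (tail percentiles plus interior percentiles,
#' deciles by default) linearly onto a standard range and averages the
#' mapped landmarks into a standard scale. Application sends each image's
#' own landmarks onto that scale by a piecewise-linear, monotone map.
#'
#' `standardization_config()` collects the tunable parameters: the tail
#' percentiles that anchor the linear stretch, the interior landmark
#' percentiles, the standard range, and the foreground rule used to exclude
#' air voxels from percentile estimation.
#'
#' @param pc_low,pc_high tail percentiles in percent (defaults 1 and 99).
#' @param landmark_percentiles strictly increasing interior percentiles
#'   (defaults: deciles 10..90).
#' @param s_min,s_max standard intensity range (defaults 0 and 4095).
#' @param fg_quantile fraction of each volume's intensities treated as
#'   non-body background and excluded from landmark estimation (e.g. 0.05
#'   to drop voxels at or below the 5th percentile on scans with an air
#'   background). The default is 0 (all voxels): the tail percentiles
#'   already make the landmarks robust, and a nonzero threshold breaks the
#'   map's idempotence because clipping at `s_min` piles mass onto the
#'   threshold after the first pass.
#' @return A list of class `standardization_config`.
#' @export
standardization_config <- function(pc_low = 1, pc_high = 99,
                                   landmark_percentiles = seq(10, 90, by = 10),
                                   s_min = 0, s_max = 4095,
                                   fg_quantile = 0) {
  stopifnot(pc_low < min(landmark_percentiles),
            pc_high > max(landmark_percentiles),
            all(diff(landmark_percentiles) > 0),
            s_min < s_max, fg_quantile >= 0, fg_quantile < 1)
  structure(list(pc_low = pc_low, pc_high = pc_high,
                 landmark_percentiles = landmark_percentiles,
                 s_min = s_min, s_max = s_max, fg_quantile = fg_quantile),
            class = "standardization_config")
}

# Foreground intensities used for landmark estimation. With a mask, the
# mask's bounding region; otherwise all voxels above the configured low
# quantile (excludes air).
standardization_foreground <- function(image, mask, config) {
  if (!is.null(mask)) {
    box <- crop_to_mask(image, mask, margin_vox = 2L)
    v <- as.vector(box$image$data)
  } else {
    v <- as.vector(image$data)
  }
  if (config$fg_quantile > 0) {
    thr <- quantile(v, config$fg_quantile, names = FALSE)
    keep <- v > thr
    if (any(keep)) v <- v[keep]  # constant volumes keep all voxels
  }
  v
}

# Landmark vector (pc_low, interior landmarks, pc_high) of one image.
image_landmarks <- function(v, config) {
  qs <- c(config$pc_low, config$landmark_percentiles, config$pc_high) / 100
  quantile(v, qs, names = FALSE, type = 7)
}

#' Train a standardization model
#'
#' For each training image the landmarks are computed on foreground voxels
#' and mapped linearly to `[s_min, s_max]`, anchored at the tail
#' percentiles. The standard scale is the per-landmark mean over training
#' images. Images with zero intensity spread between the tails are excluded
#' with a warning; if all are excluded this is an error.
#'
#' @param images list of [volume_image()].
#' @param masks optional list of [wall_mask()] (same length); when given,
#'   landmarks are estimated inside each mask's bounding region.
#' @param config a [standardization_config()].
#' @param prestep optional inhomogeneity-correction hook: a function
#'   `volume_image -> volume_image` applied to each image before landmark
#'   estimation (and again before mapping in [apply_standardizer()]).
#'   Default `NULL`: synthetic phantoms carry no bias field; plug in an
#'   external corrector for real scans.
#' @return A list of class `standardization_model` holding the config and
#'   the learned `standard_scale` (length `k + 2` including the anchors).
#' @export
train_standardizer <- function(images, masks = NULL,
                               config = standardization_config(),
                               prestep = NULL) {
  stopifnot(length(images) >= 1)
  if (!is.null(masks)) stopifnot(length(masks) == length(images))
  mapped <- list()
  for (i in seq_along(images)) {
    img_i <- if (is.null(prestep)) images[[i]] else prestep(images[[i]])
    v <- standardization_foreground(img_i,
                                    if (is.null(masks)) NULL else masks[[i]],
                                    config)
    lm <- image_landmarks(v, config)
    span <- lm[length(lm)] - lm[1]
    if (!is.finite(span) || span <= 0) {
      warning(sprintf("training image %d has zero intensity spread; excluded", i))
      next
    }
    mapped[[length(mapped) + 1]] <-
      config$s_min + (lm - lm[1]) / span * (config$s_max - config$s_min)
  }
  if (!length(mapped))
    stop("all training images excluded: no intensity spread")
  scale <- colMeans(do.call(rbind, mapped))
  scale[1] <- config$s_min
  scale[length(scale)] <- config$s_max
  if (any(diff(scale) <= 0))
    stop("degenerate standard scale: landmarks not strictly increasing")
  structure(list(config = config, standard_scale = unname(scale),
                 n_train = length(mapped)),
            class = "standardization_model")
}

# Monotone piecewise-linear map through (src, dst) knots; outside the knot
# range the end segments extrapolate linearly, then values are clipped.
piecewise_linear_map <- function(x, src, dst, clip_lo, clip_hi) {
  # collapse numerically tied source knots (can happen for quantized data)
  keep <- c(TRUE, diff(src) > .Machine$double.eps * max(abs(src), 1))
  src <- src[keep]; dst <- dst[keep]
  if (length(src) < 2) stop("zero intensity spread: cannot standardize")
  y <- approx(src, dst, xout = x, rule = 2)$y
  lo <- x < src[1]
  if (any(lo)) {
    s <- (dst[2] - dst[1]) / (src[2] - src[1])
    y[lo] <- dst[1] + (x[lo] - src[1]) * s
  }
  k <- length(src)
  hi <- x > src[k]
  if (any(hi)) {
    s <- (dst[k] - dst[k - 1]) / (src[k] - src[k - 1])
    y[hi] <- dst[k] + (x[hi] - src[k]) * s
  }
  pmin(pmax(y, clip_lo), clip_hi)
}

#' Apply a standardization model to a volume
#'
#' Sends the image's own landmarks onto the model's standard scale with a
#' monotone piecewise-linear map; values beyond the tails are extrapolated
#' from the end segments, then clipped to the standard range. Spacing is
#' unchanged.
#'
#' @param model a `standardization_model` from [train_standardizer()].
#' @param image a [volume_image()].
#' @param mask optional [wall_mask()] to localize landmark estimation.
#' @param prestep optional inhomogeneity-correction hook (see
#'   [train_standardizer()]); use the same hook in both phases.
#' @return A standardized [volume_image()].
#' @export
apply_standardizer <- function(model, image, mask = NULL, prestep = NULL) {
  if (!is.null(prestep)) image <- prestep(image)
  cfg <- model$config
  v <- standardization_foreground(image, mask, cfg)
  lm <- image_landmarks(v, cfg)
  if (lm[length(lm)] - lm[1] <= 0)
    stop("zero intensity spread: cannot standardize")
  out <- piecewise_linear_map(as.vector(image$data), lm, model$standard_scale,
                              cfg$s_min, cfg$s_max)
  volume_image(array(out, image$shape), image$spacing)
}

#' Serialize / restore a standardization model as JSON
#' @param model a `standardization_model`.
#' @param path JSON file path.
#' @return `write_standardizer` returns `path` invisibly;
#'   `read_standardizer` the restored model.
#' @export
write_standardizer <- function(model, path) {
  jsonlite::write_json(list(config = unclass(model$config),
                            standard_scale = model$standard_scale,
                            n_train = model$n_train),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_standardizer
#' @export
read_standardizer <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(standardization_config, x$config)
  structure(list(config = cfg, standard_scale = x$standard_scale,
                 n_train = x$n_train),
            class = "standardization_model")
}
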