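#' Quantize intensities to gray levels
#'
#' Equal-width binning over a fixed range, the prerequisite of gray-level
#' co-occurrence analysis. The default range policy is robust: the 1st and
#' 99th percentile of in-mask intensities, with values outside clipped into
#' range, so a few extreme voxels cannot stretch the bins.
#'
#' @param x numeric vector or array of intensities.
#' @param bins number of gray levels `b >= 2`.
#' @param range length-2 numeric range, or `NULL` to derive it from
#'   `range_policy` over `x` (in-mask values only, if `mask` given).
#' @param mask optional logical/0-1 array selecting the voxels that define
#'   the robust range.
#' @param range_policy `"robust"` (`[p1, p99]`) or `"full"` (min/max).
#' @return Integer array (same shape as `x`) of levels in `[0, bins - 1]`.
#'   A zero-width range degenerates gracefully: every value maps to level 0.
#' @export
quantize <- function(x, bins, range = NULL, mask = NULL,
                     range_policy = c("robust", "full")) {
  stopifnot(bins >= 2)
  range_policy <- match.arg(range_policy)
  v <- if (!is.null(mask)) x[mask != 0] else x
  if (is.null(range)) {
    range <- if (range_policy == "robust")
      quantile(v, c(0.01, 0.99), names = FALSE) else base::range(v)
  }
  lo <- range[1]; hi <- range[2]
  if (hi - lo <= 0) {
    lev <- rep(0L, length(x))
  } else {
    z <- pmin(pmax(x, lo), hi)
    lev <- as.integer(pmin(floor((z - lo) / (hi - lo) * bins), bins - 1))
  }
  if (!is.null(dim(x))) dim(lev) <- dim(x)
  lev
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream (seeded internals must not make unrelated randomness collapse)
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

# Lattice offset for a co-occurrence direction. 2D angles are in-plane
# degrees over the first two array axes: 0 steps along axis 1, 90 along
# axis 2, 45/135 the diagonals. 3D directions index the 13 unique lattice
# directions of the half-neighbourhood.
glcm_offset <- function(angle, ndim = 2L) {
  if (length(angle) > 1) return(as.integer(angle))
  if (ndim == 2L) {
    switch(as.character(angle),
           "0" = c(1L, 0L), "45" = c(1L, 1L), "90" = c(0L, 1L),
           "135" = c(-1L, 1L),
           stop("2D angle must be one of 0, 45, 90, 135 degrees"))
  } else {
    dirs <- rbind(c(1,0,0), c(0,1,0), c(0,0,1),
                  c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1),
                  c(0,1,1), c(0,1,-1),
                  c(1,1,1), c(1,-1,1), c(1,1,-1), c(1,-1,-1))
    i <- as.integer(angle)
    if (i < 1 || i > 13) stop("3D direction index must be in 1..13")
    as.integer(dirs[i, ])
  }
}

#' Gray-level co-occurrence matrix
#'
#' Counts pairs of quantized levels at a fixed lattice offset. A pair
#' counts only when both voxels lie in the mask. With `symmetric = TRUE`
#' the matrix is added to its transpose (each pair counted in both
#' directions); with `normalize = TRUE` entries sum to 1.
#'
#' @param levels integer array (2D or 3D) of gray levels in
#'   `[0, nbins - 1]`.
#' @param mask logical/0-1 array of the same shape; `NULL` means all voxels.
#' @param angle direction: in 2D one of 0/45/90/135 (degrees); in 3D an
#'   index 1..13 into the unique lattice directions; or an explicit integer
#'   offset vector.
#' @param distance offset multiplier in voxels (`d >= 1`).
#' @param nbins number of gray levels `b`.
#' @param symmetric,normalize see Description.
#' @return `nbins x nbins` numeric matrix. If no valid pair exists the zero
#'   matrix is returned with attribute `empty = TRUE`.
#' @export
glcm <- function(levels, mask = NULL, angle = 0, distance = 1L, nbins,
                 symmetric = TRUE, normalize = TRUE) {
  stopifnot(distance >= 1)
  d <- dim(levels)
  nd <- length(d)
  stopifnot(nd %in% c(2L, 3L))
  if (is.null(mask)) mask <- array(TRUE, d)
  off <- glcm_offset(angle, nd) * as.integer(distance)
  # source index window such that source + offset stays in bounds
  rng <- lapply(seq_len(nd), function(k) {
    lo <- max(1L, 1L - off[k]); hi <- min(d[k], d[k] - off[k])
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(!lengths(rng))) {
    m <- matrix(0, nbins, nbins); attr(m, "empty") <- TRUE; return(m)
  }
  take <- function(x, shift) {
    idx <- lapply(seq_len(nd), function(k) rng[[k]] + shift[k])
    do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  }
  li <- take(levels, integer(nd)); lj <- take(levels, off)
  ok <- take(mask, integer(nd)) != 0 & take(mask, off) != 0 &
    li >= 0 & li < nbins & lj >= 0 & lj < nbins
  li <- li[ok]; lj <- lj[ok]
  if (!length(li)) {
    m <- matrix(0, nbins, nbins); attr(m, "empty") <- TRUE; return(m)
  }
  counts <- tabulate(li * nbins + lj + 1L, nbins * nbins)
  m <- matrix(as.numeric(counts), nbins, nbins, byrow = TRUE)
  if (symmetric) m <- m + t(m)
  if (normalize) m <- m / sum(m)
  m
}

#' Haralick texture features of a normalized GLCM
#'
#' Standard second-order statistics of the co-occurrence distribution
#' `p(i, j)` (0-based level indices). `entropy` uses log base 2 with the
#' convention `0 * log 0 = 0`; `correlation` is defined as 0 when either
#' marginal SD is 0.
#'
#' @param p normalized co-occurrence matrix (entries sum to 1).
#' @param feature one or more of contrast, dissimilarity, homogeneity,
#'   energy, entropy, correlation, variance, sum_average, cluster_shade,
#'   cluster_prominence (see [haralick_features()]).
#' @return Named numeric vector of the requested features; `NaN` for an
#'   empty (all-zero) matrix.
#' @export
haralick <- function(p, feature = haralick_features()) {
  feature <- match.arg(feature, haralick_features(), several.ok = TRUE)
  b <- nrow(p)
  if (sum(p) == 0 || isTRUE(attr(p, "empty")))
    return(structure(rep(NaN, length(feature)), names = feature))
  i <- matrix(0:(b - 1), b, b)          # row index (first level)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mx <- sum((0:(b - 1)) * px); my <- sum((0:(b - 1)) * py)
  sx <- sqrt(sum(((0:(b - 1)) - mx)^2 * px))
  sy <- sqrt(sum(((0:(b - 1)) - my)^2 * py))
  out <- vapply(feature, function(f) {
    switch(f,
      contrast = sum(p * (i - j)^2),
      dissimilarity = sum(p * abs(i - j)),
      homogeneity = sum(p / (1 + (i - j)^2)),
      energy = sum(p^2),
      entropy = { q <- p[p > 0]; -sum(q * log2(q)) },
      correlation = if (sx == 0 || sy == 0) 0 else
        sum((i - mx) * (j - my) * p) / (sx * sy),
      variance = sum((i - mx)^2 * p),
      sum_average = sum((i + j) * p),
      cluster_shade = sum((i + j - mx - my)^3 * p),
      cluster_prominence = sum((i + j - mx - my)^4 * p))
  }, numeric(1))
  out
}

#' The Haralick feature names computed by this package
#' @return Character vector of the ten supported feature names.
#' @export
haralick_features <- function() {
  c("contrast", "dissimilarity", "homogeneity", "energy", "entropy",
    "correlation", "variance", "sum_average", "cluster_shade",
    "cluster_prominence")
}
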