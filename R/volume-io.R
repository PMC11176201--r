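#' Construct a 3D scalar volume with voxel spacing
#'
#' A `volume_image` is the package's in-memory representation of one MR
#' volume: a 3D numeric array plus voxel spacing in mm. All pipeline
#' operations work in 0-based voxel indices with axis order (x, y, z) as
#' stored by the reader; spacing is consulted only where physical units are
#' required (morphometry, phantom construction).
#'
#' @param data 3D numeric array of intensities (arbitrary MR units).
#' @param spacing numeric length-3, voxel edge lengths (sx, sy, sz) in mm,
#'   all strictly positive.
#' @return An object of class `volume_image` with elements `data`, `spacing`
#'   and `shape`.
#' @examples
#' v <- volume_image(array(1, c(4, 4, 4)), spacing = c(1, 1, 1))
#' v$shape
#' @export
volume_image <- function(data, spacing = c(1, 1, 1)) {
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) != 3L)
    stop("expected 3D volume, got ", length(dim(data)), "D array")
  if (!is.numeric(data))
    stop("volume data must be numeric")
  if (!all(is.finite(data)))
    stop("volume contains non-finite intensities")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm); got: ",
         paste(format(spacing), collapse = " x "))
  structure(list(data = data, spacing = spacing, shape = dim(data)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a hollow wall mask on the lattice of a volume
#'
#' A `wall_mask` is a binary 3D array marking a hollow shell: a connected
#' wall of foreground voxels enclosing at least one cavity (a background
#' component with no path to the grid border, 6-connectivity). The cavity
#' corresponds to the organ lumen, the wall to the tissue between inner and
#' outer surfaces.
#'
#' @param data 3D array; nonzero entries become foreground.
#' @param image the paired [volume_image()]; shapes must agree.
#' @param check_hollow verify the hollow-shell invariant (default `TRUE`).
#' @return An object of class `wall_mask` with elements `data` (integer 0/1
#'   array) and `spacing`.
#' @export
wall_mask <- function(data, image, check_hollow = TRUE) {
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) != 3L)
    stop("expected 3D mask, got ", length(dim(data)), "D array")
  if (!identical(dim(data), image$shape))
    stop("mask grid ", paste(dim(data), collapse = "x"),
         " does not match image grid ", paste(image$shape, collapse = "x"))
  m <- array(as.integer(data != 0), dim(data))
  if (sum(m) == 0L) stop("empty mask: no foreground voxels")
  if (check_hollow && !has_enclosed_cavity(m))
    stop("mask is not a hollow shell: no enclosed cavity")
  structure(list(data = m, spacing = image$spacing), class = "wall_mask")
}

#' @export
print.wall_mask <- function(x, ...) {
  cat(sprintf("<wall_mask> %s voxels, %d foreground\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

# Border-connected background by iterative 6-neighbour frontier propagation.
# Returns a logical array: TRUE where background reachable from the border.
border_connected_background <- function(mask_data) {
  d <- dim(mask_data)
  bg <- mask_data == 0L
  reach <- array(FALSE, d)
  # seed: background voxels on any face of the grid
  reach[1, , ] <- bg[1, , ]; reach[d[1], , ] <- bg[d[1], , ]
  reach[, 1, ] <- reach[, 1, ] | bg[, 1, ]; reach[, d[2], ] <- reach[, d[2], ] | bg[, d[2], ]
  reach[, , 1] <- reach[, , 1] | bg[, , 1]; reach[, , d[3]] <- reach[, , d[3]] | bg[, , d[3]]
  repeat {
    grown <- reach
    grown[-1, , ]   <- grown[-1, , ]   | reach[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | reach[-1, , ]
    grown[, -1, ]   <- grown[, -1, ]   | reach[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | reach[, -1, ]
    grown[, , -1]   <- grown[, , -1]   | reach[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | reach[, , -1]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  reach
}

# A mask encloses a cavity iff some background voxel is unreachable from the
# grid border through background (6-connectivity).
has_enclosed_cavity <- function(mask_data) {
  bg <- mask_data == 0L
  any(bg & !border_connected_background(mask_data))
}

#' Read a 3D scalar NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file holding a 3D scalar image.
#' @return A [volume_image()] with spacing taken from the NIfTI `pixdim`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) != 3L)
    stop("expected 3D volume in ", path, "; header dim gives ",
         length(dim(a)), "D data")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in NIfTI header field pixdim: ",
         paste(format(sp), collapse = " x "))
  volume_image(a + 0, spacing = sp)
}

#' Write a volume (or mask) as NIfTI
#'
#' @param x a [volume_image()] or [wall_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  dat <- if (inherits(x, "wall_mask")) x$data + 0 else x$data
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a wall mask paired with its volume
#'
#' Values are binarized (nonzero becomes foreground) and the hollow-shell
#' invariant is verified: the foreground must enclose at least one cavity
#' not connected to the grid border.
#'
#' @param path path to the mask NIfTI.
#' @param image the already-read [volume_image()] sharing the lattice.
#' @return A [wall_mask()].
#' @export
read_mask <- function(path, image) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
  wall_mask(a, image)
}

#' Crop an image and mask to the mask's bounding box
#'
#' Computes the tight bounding box of mask foreground, expands it by
#' `margin_vox` voxels per side, clips to the grid, and crops image and mask
#' identically. Spacing is unchanged and no foreground voxel is discarded.
#'
#' @param image a [volume_image()].
#' @param mask the paired [wall_mask()].
#' @param margin_vox non-negative integer margin, in voxels.
#' @return A list with elements `image` and `mask`, cropped.
#' @export
crop_to_mask <- function(image, mask, margin_vox = 0L) {
  stopifnot(margin_vox >= 0)
  idx <- which(mask$data != 0L, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - margin_vox, 1L)
  hi <- pmin(apply(idx, 2, max) + margin_vox, dim(mask$data))
  sl <- lapply(1:3, function(k) lo[k]:hi[k])
  im <- volume_image(image$data[sl[[1]], sl[[2]], sl[[3]], drop = FALSE],
                     image$spacing)
  mk <- wall_mask(mask$data[sl[[1]], sl[[2]], sl[[3]], drop = FALSE],
                  im, check_hollow = FALSE)
  list(image = im, mask = mk)
}
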