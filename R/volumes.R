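# Volume containers, NIfTI I/O, Gaussian smoothing, gray-matter masking.

#' Construct a 3D volume
#'
#' A `volume3d` couples a numeric voxel grid with a 4x4 affine that maps
#' 0-based voxel indices `(i, j, k, 1)` to world millimetre coordinates.
#'
#' @param data Numeric 3D array of voxel values; all values must be finite.
#' @param affine 4x4 voxel-to-world transform (last row `c(0, 0, 0, 1)`).
#' @return An object of class `volume3d` with elements `data` and `affine`.
#' @export
volume3d <- function(data, affine = default_affine(dim(data))) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  check_affine(affine)
  if (!all(is.finite(data)))
    stop("volume3d: data contains non-finite values")
  structure(list(data = data, affine = affine), class = "volume3d")
}

#' Construct a 4D volume (BOLD time series)
#'
#' @param data Numeric 4D array indexed `(i, j, k, t)` with at least 2 frames.
#' @param affine 4x4 voxel-to-world transform for the spatial axes.
#' @param tr_seconds Repetition time (sampling interval) in seconds; must be
#'   positive.
#' @return An object of class `volume4d`.
#' @export
volume4d <- function(data, affine = default_affine(dim(data)[1:3]),
                     tr_seconds = 2) {
  stopifnot(is.array(data), length(dim(data)) == 4)
  check_affine(affine)
  if (dim(data)[4] < 2)
    stop("volume4d: time dimension must have at least 2 frames")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0)
    stop("volume4d: tr_seconds must be a single positive number")
  if (!all(is.finite(data)))
    stop("volume4d: data contains non-finite values")
  structure(list(data = data, affine = affine, tr_seconds = tr_seconds),
            class = "volume4d")
}

default_affine <- function(dim3, voxel_size = c(3, 3, 3)) {
  aff <- diag(c(voxel_size, 1))
  # centre the grid on the world origin
  aff[1:3, 4] <- -voxel_size * (dim3 - 1) / 2
  aff
}

check_affine <- function(affine) {
  if (!is.matrix(affine) || !identical(dim(affine), c(4L, 4L)) ||
      !all(is.finite(affine)))
    stop("affine must be a finite 4x4 matrix")
  if (!isTRUE(all.equal(affine[4, ], c(0, 0, 0, 1))))
    stop("affine last row must be (0, 0, 0, 1)")
  invisible(affine)
}

#' Voxel size implied by an affine
#'
#' Millimetres per axis, taken as the Euclidean norms of the affine's first
#' three columns.
#'
#' @param x A `volume3d`, `volume4d`, or 4x4 affine matrix.
#' @return Numeric vector of length 3 (mm per spatial axis).
#' @export
voxel_size <- function(x) {
  aff <- if (is.matrix(x)) x else x$affine
  sqrt(colSums(aff[1:3, 1:3]^2))
}

#' Map 1-based voxel indices to world mm coordinates
#'
#' Follows the NIfTI convention of 0-based voxel indices: world
#' `= affine %*% c(i - 1, j - 1, k - 1, 1)`.
#'
#' @param ijk Integer matrix (n x 3) or vector of length 3, 1-based indices.
#' @param affine 4x4 voxel-to-world transform.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3)
  h <- cbind(ijk - 1, 1)
  xyz <- h %*% t(affine)
  xyz[, 1:3, drop = FALSE]
}

#' Read a NIfTI volume
#'
#' Reads a 3D or 4D NIfTI-1 image into a [volume3d()] or [volume4d()]. The
#' affine is taken from the image xform (sform preferred); for 4D images the
#' repetition time comes from the 4th pixdim entry.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `volume3d` or `volume4d` depending on image dimensionality.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  aff <- unname(matrix(unclass(RNifti::xform(img)), 4, 4))
  arr <- array(as.vector(img), dim = d)
  if (length(d) == 3) {
    volume3d(arr, aff)
  } else if (length(d) == 4) {
    tr <- RNifti::pixdim(img)[4]
    if (!is.finite(tr) || tr <= 0) tr <- 1
    volume4d(arr, aff, tr_seconds = tr)
  } else {
    stop("read_volume: unsupported dimensionality (", length(d),
         "D); expected a 3D or 4D image")
  }
}

#' Write a volume to NIfTI
#'
#' @param vol A `volume3d` or `volume4d`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  UseMethod("write_volume")
}

nifti_from <- function(data, affine, tr = NULL) {
  img <- RNifti::asNifti(data)
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- if (is.null(tr)) vs else c(vs, tr)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  img
}

#' @export
write_volume.volume3d <- function(vol, path) {
  RNifti::writeNifti(nifti_from(vol$data, vol$affine), path)
  invisible(path)
}

#' @export
write_volume.volume4d <- function(vol, path) {
  RNifti::writeNifti(nifti_from(vol$data, vol$affine, tr = vol$tr_seconds),
                     path)
  invisible(path)
}

# --- Gaussian smoothing ------------------------------------------------------

fwhm_to_sigma <- function(fwhm_mm, voxel_size_mm) {
  fwhm_mm / (voxel_size_mm * 2 * sqrt(2 * log(2)))
}

# 1D Gaussian kernel truncated at 4 sigma, normalised to unit mass
gauss_kernel <- function(sigma_vox) {
  r <- ceiling(4 * sigma_vox)
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Band convolution matrix for one axis under zero padding
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (off in seq(-r, r)) {
    idx <- which(seq_len(n) + off >= 1 & seq_len(n) + off <= n)
    K[cbind(idx, idx + off)] <- kernel[off + r + 1L]
  }
  K
}

# Apply a 1D kernel along one axis of a 3D or 4D array (zero padding)
smooth_axis <- function(arr, axis, kernel) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  m <- conv_matrix(d[axis], kernel) %*% m
  aperm(array(m, dim = d[perm]), order(perm))
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian convolution with per-axis sigma
#' `fwhm / (voxel_size * 2 * sqrt(2 * log(2)))`, kernel truncated at 4 sigma,
#' zero padding at the grid boundary (the background convention of common
#' neuroimaging smoothers). 4D volumes are smoothed frame by frame over the
#' spatial axes only. `fwhm_mm = 0` returns the input unchanged.
#'
#' @param vol A `volume3d` or `volume4d`.
#' @param fwhm_mm Full width at half maximum of the kernel, in mm (>= 0).
#' @return Smoothed volume of the same class and shape.
#' @export
gaussian_smooth <- function(vol, fwhm_mm) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1 || fwhm_mm < 0)
    stop("gaussian_smooth: fwhm_mm must be a single non-negative number")
  UseMethod("gaussian_smooth")
}

smooth_array <- function(arr, fwhm_mm, vs) {
  for (ax in 1:3) {
    sigma <- fwhm_to_sigma(fwhm_mm, vs[ax])
    if (sigma > 0) arr <- smooth_axis(arr, ax, gauss_kernel(sigma))
  }
  arr
}

#' @export
gaussian_smooth.volume3d <- function(vol, fwhm_mm) {
  if (fwhm_mm == 0) return(vol)
  vol$data <- smooth_array(vol$data, fwhm_mm, voxel_size(vol))
  vol
}

#' @export
gaussian_smooth.volume4d <- function(vol, fwhm_mm) {
  if (fwhm_mm == 0) return(vol)
  vol$data <- smooth_array(vol$data, fwhm_mm, voxel_size(vol))
  vol
}

# --- Gray-matter mask --------------------------------------------------------

#' Build a gray-matter analysis mask
#'
#' Smooths a gray-matter probability volume and keeps voxels whose smoothed
#' probability reaches a minimum threshold. The retained voxels get a fixed
#' linear ordering (ascending column-major index, first axis fastest) that
#' defines the row order of every downstream voxel-by-time matrix.
#'
#' @param gm_prob `volume3d` of tissue probabilities in `[0, 1]`.
#' @param smooth_fwhm_mm FWHM for pre-threshold smoothing (default 4 mm).
#' @param threshold Minimum smoothed probability for inclusion (default 0.12).
#' @return An object of class `gm_mask` with elements `include` (logical
#'   array), `ordering` (linear indices of included voxels), `n_voxels`,
#'   `dim`, and `affine`.
#' @export
make_gm_mask <- function(gm_prob, smooth_fwhm_mm = 4, threshold = 0.12) {
  stopifnot(inherits(gm_prob, "volume3d"))
  if (any(gm_prob$data < 0 | gm_prob$data > 1))
    stop("make_gm_mask: probabilities must lie in [0, 1]")
  sm <- gaussian_smooth(gm_prob, smooth_fwhm_mm)
  include <- sm$data >= threshold
  ordering <- which(include)
  if (length(ordering) == 0)
    stop("make_gm_mask: mask is empty (no voxel reaches probability ",
         threshold, " after smoothing)")
  structure(list(include = include, ordering = ordering,
                 n_voxels = length(ordering), dim = dim(gm_prob$data),
                 affine = gm_prob$affine),
            class = "gm_mask")
}

#' @export
print.gm_mask <- function(x, ...) {
  cat("<gm_mask> ", x$n_voxels, " voxels on a ",
      paste(x$dim, collapse = "x"), " grid\n", sep = "")
  invisible(x)
}

#' Write a mask as uint8 NIfTI
#'
#' @param mask A `gm_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  img <- nifti_from(array(as.integer(mask$include), dim = mask$dim),
                    mask$affine)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Extract the masked voxel-by-time matrix
#'
#' @param vol4d A `volume4d` whose spatial shape matches the mask.
#' @param mask A `gm_mask`.
#' @return Numeric matrix with `mask$n_voxels` rows (in `mask$ordering`
#'   order) and one column per frame.
#' @export
extract_timeseries <- function(vol4d, mask) {
  stopifnot(inherits(vol4d, "volume4d"), inherits(mask, "gm_mask"))
  d <- dim(vol4d$data)
  if (!identical(d[1:3], as.integer(mask$dim)))
    stop("extract_timeseries: spatial shape ", paste(d[1:3], collapse = "x"),
         " does not match mask shape ", paste(mask$dim, collapse = "x"))
  m <- matrix(vol4d$data, nrow = prod(d[1:3]), ncol = d[4])
  m[mask$ordering, , drop = FALSE]
}

#' Scatter per-voxel values back into a volume
#'
#' Inverse of [extract_timeseries()] for a single map: in-mask voxels receive
#' `values` (in mask ordering), background voxels are exactly 0.
#'
#' @param values Numeric vector of length `mask$n_voxels`.
#' @param mask A `gm_mask`.
#' @return A `volume3d`.
#' @export
scatter_to_volume <- function(values, mask) {
  stopifnot(inherits(mask, "gm_mask"), length(values) == mask$n_voxels)
  arr <- array(0, dim = mask$dim)
  arr[mask$ordering] <- values
  volume3d(arr, mask$affine)
}

#' World mm coordinates of in-mask voxel centres
#'
#' @param mask A `gm_mask`.
#' @return `n_voxels` x 3 matrix, rows in mask ordering.
#' @export
mask_coordinates <- function(mask) {
  ijk <- arrayInd(mask$ordering, mask$dim)
  voxel_to_world(ijk, mask$affine)
}
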