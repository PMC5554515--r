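#' 3D scalar volume with grid metadata
#'
#' A `volume_image` is a 3D array of finite scalars (PET activity, a bias
#' field, or a logical mask) together with the voxel spacing (mm per axis)
#' and the world coordinate (mm) of the first voxel center. Two images are
#' grid-compatible iff shape, spacing and origin all match. World
#' coordinates follow the voxel-center convention
#' `world = origin + (index - 1) * spacing` with R's 1-based indices.
#'
#' @param values 3D numeric or logical array.
#' @param spacing Numeric length-3, mm per axis; all > 0.
#' @param origin Numeric length-3, mm world coordinate of voxel (1,1,1).
#' @return A `volume_image` object.
#' @export
volume_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  if (is.numeric(values) && any(!is.finite(values)))
    stop("`values` must be finite everywhere")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_image> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  if (is.logical(x$values))
    cat(sprintf("  logical mask: %d voxels set (%.2f mL)\n",
                sum(x$values), mask_volume_ml(x)))
  else
    cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Test grid compatibility of two volumes
#'
#' @param a,b `volume_image` objects.
#' @return `TRUE` iff shape, spacing and origin match exactly.
#' @export
same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 0)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 0))
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf(
      "grid mismatch between %s: [%s | %s | %s] vs [%s | %s | %s]", what,
      paste(dim(a$values), collapse = "x"), paste(a$spacing, collapse = ","),
      paste(a$origin, collapse = ","),
      paste(dim(b$values), collapse = "x"), paste(b$spacing, collapse = ","),
      paste(b$origin, collapse = ",")))
  invisible(TRUE)
}

#' Voxel volume in mL
#' @param x A `volume_image`.
#' @return Volume of one voxel in mL (spacings are mm, 1 mL = 1000 mm^3).
#' @export
voxel_volume_ml <- function(x) prod(x$spacing) / 1000

#' Volume of a binary mask in mL
#' @param x A logical `volume_image`.
#' @return Total masked volume in mL.
#' @export
mask_volume_ml <- function(x) sum(x$values) * voxel_volume_ml(x)

# World coordinates (mm) of a 1-based voxel index triple.
voxel_to_world <- function(x, index) x$origin + (as.numeric(index) - 1) * x$spacing

# Array of world coordinates along one axis.
axis_world <- function(x, axis) {
  n <- dim(x$values)[axis]
  x$origin[axis] + (seq_len(n) - 1) * x$spacing[axis]
}

#' Read a NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file into a [volume_image], taking spacing from
#' the pixdim and origin from the stored affine's translation. Orientation
#' is assumed axis-aligned (as written by [write_volume]).
#'
#' @param path File path.
#' @param mask Logical; coerce values to logical (nonzero = TRUE)?
#' @return A `volume_image`.
#' @export
read_volume <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  aff <- RNifti::xform(img)
  spacing <- abs(diag(aff)[1:3])
  origin <- aff[1:3, 4]
  if (mask) arr <- arr != 0
  dim(arr) <- dim(arr)
  volume_image(arr, spacing = spacing, origin = origin)
}

#' Write a NIfTI volume
#'
#' Writes a [volume_image] (scalar or logical mask) as NIfTI with a diagonal
#' affine carrying spacing and origin. Masks are stored as 8-bit integers.
#'
#' @param x A `volume_image`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  vals <- x$values
  datatype <- "double"
  if (is.logical(vals)) { vals <- array(as.integer(vals), dim(vals)); datatype <- "uint8" }
  attr(vals, "pixdim") <- x$spacing
  aff <- diag(4)
  diag(aff)[1:3] <- x$spacing
  aff[1:3, 4] <- x$origin
  img <- RNifti::asNifti(vals, datatype = datatype)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Label 26-connected components of a 3D mask
#'
#' @param mask Logical `volume_image` or 3D logical array.
#' @return Integer array of the same shape; 0 = background, components
#'   numbered from 1 in deterministic (first-voxel linear index) order.
#' @export
label_components <- function(mask) {
  arr <- if (inherits(mask, "volume_image")) mask$values else mask
  cpp_label_components(as.logical(arr), as.integer(dim(arr)))
}

#' Euclidean distance to the mask edge
#'
#' For each voxel inside the mask, the exact anisotropic Euclidean distance
#' (mm) to the nearest voxel center outside the mask; 0 outside.
#'
#' @param mask Logical `volume_image`.
#' @return Numeric array of distances (mm).
#' @export
distance_to_edge <- function(mask) {
  cpp_edt(as.logical(mask$values), as.integer(dim(mask$values)),
          as.numeric(mask$spacing))
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter with full-width-at-half-maximum given in mm;
#' values beyond the array edge are treated as zero.
#'
#' @param x A `volume_image` (numeric values).
#' @param fwhm_mm Full width at half maximum of the kernel, mm.
#' @return A `volume_image` of smoothed values on the same grid.
#' @export
gaussian_smooth <- function(x, fwhm_mm) {
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / x$spacing
  sm <- cpp_gaussian_smooth(as.numeric(x$values), as.integer(dim(x$values)),
                            as.numeric(sigma_vox))
  volume_image(sm, spacing = x$spacing, origin = x$origin)
}
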