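#' Binary voxel mask on an anisotropic grid
#'
#' The carrier of all contour geometry in the package: a 3D logical array of
#' voxels together with the physical voxel size (mm per axis) and the world
#' coordinate of the center of voxel `[1, 1, 1]`.
#'
#' @param voxels 3D logical array (`TRUE` = foreground).
#' @param spacing_mm numeric length 3, voxel size in mm per axis; strictly
#'   positive and finite.
#' @param origin_mm numeric length 3, world coordinate (mm) of the center of
#'   the first voxel.
#' @return An object of class `binary_mask`.
#' @examples
#' v <- array(FALSE, c(8, 8, 8)); v[3:5, 3:5, 3:5] <- TRUE
#' m <- binary_mask(v, spacing_mm = c(2, 2, 2))
#' mask_volume_ml(m)
#' @export
binary_mask <- function(voxels, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  if (is.logical(voxels) && is.null(dim(voxels)))
    stop("`voxels` must be a 3D array")
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (!is.logical(voxels)) {
    storage.mode(voxels) <- "logical"
  }
  if (anyNA(voxels)) stop("`voxels` must not contain NA")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 finite, strictly positive values")
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be 3 finite values")
  if (any(dim(voxels) < 1L)) stop("all axes must have length >= 1")
  structure(list(voxels = voxels, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, spacing %s mm, %d foreground\n",
              d[1], d[2], d[3], paste(format(x$spacing_mm), collapse = " x "),
              sum(x$voxels)))
  invisible(x)
}

is_binary_mask <- function(x) inherits(x, "binary_mask")

#' Foreground volume of a mask in millilitres
#' @param mask a [binary_mask()].
#' @return volume in ml.
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(is_binary_mask(mask))
  sum(mask$voxels) * prod(mask$spacing_mm) / 1000
}

check_same_grid <- function(a, b) {
  if (!is_binary_mask(a) || !is_binary_mask(b))
    stop("both arguments must be binary_mask objects")
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("masks have different grid shapes: ",
         paste(dim(a$voxels), collapse = "x"), " vs ",
         paste(dim(b$voxels), collapse = "x"))
  if (max(abs(a$spacing_mm - b$spacing_mm)) > 1e-9)
    stop("masks have different voxel spacings")
  invisible(TRUE)
}

# Shift a logical array by one voxel along `axis` (direction +1/-1), padding
# with FALSE, so voxels at the grid edge see background outside the grid.
shift_logical <- function(v, axis, dir) {
  d <- dim(v)
  out <- array(FALSE, d)
  n <- d[axis]
  if (n == 1L) return(out)
  src <- dst <- list(quote(expr =), quote(expr =), quote(expr =))
  if (dir > 0) { dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
  else { dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1) }
  out <- do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(v), src)))))
  out
}

#' Boundary voxels of a mask
#'
#' A foreground voxel is a boundary voxel when at least one of its six
#' face-adjacent neighbours is background, counting positions outside the grid
#' as background (so foreground touching the grid edge is boundary).
#'
#' @param mask a [binary_mask()].
#' @return 3D logical array flagging boundary voxels.
#' @export
mask_boundary <- function(mask) {
  stopifnot(is_binary_mask(mask))
  v <- mask$voxels
  interior <- v
  for (axis in 1:3) for (dir in c(1L, -1L))
    interior <- interior & shift_logical(v, axis, dir)
  v & !interior
}

# Euclidean distance (mm) from every voxel center to the nearest TRUE voxel
# center. Inf where the target set is empty.
edt_mm <- function(voxels, spacing_mm) {
  .edt3d_cpp(as.logical(voxels), as.integer(dim(voxels)), as.numeric(spacing_mm))
}

# World coordinates (mm) of voxel centers along each axis.
grid_axes_mm <- function(dim3, spacing_mm, origin_mm = c(0, 0, 0)) {
  lapply(1:3, function(a) origin_mm[a] + (seq_len(dim3[a]) - 1) * spacing_mm[a])
}

#' Write a mask to a NIfTI file
#'
#' Voxels are stored as 0/1 integers; the voxel spacing goes into `pixdim` and
#' the origin into the qform/sform translation.
#'
#' @param mask a [binary_mask()].
#' @param path output filename (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(is_binary_mask(mask))
  img <- array(as.integer(mask$voxels), dim(mask$voxels))
  nii <- RNifti::asNifti(img)
  RNifti::pixdim(nii) <- mask$spacing_mm
  xf <- diag(c(mask$spacing_mm, 1))
  xf[1:3, 4] <- mask$origin_mm
  nii <- RNifti::`sform<-`(nii, structure(xf, code = 2L))
  nii <- RNifti::`qform<-`(nii, structure(xf, code = 2L))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read a mask from a NIfTI file
#'
#' Any strictly positive voxel value is taken as foreground.
#'
#' @param path NIfTI filename.
#' @return a [binary_mask()].
#' @export
read_mask_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii) > 0
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  xf <- RNifti::xform(nii)
  sp <- sqrt(colSums(xf[1:3, 1:3]^2))
  binary_mask(arr, spacing_mm = sp, origin_mm = xf[1:3, 4])
}
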