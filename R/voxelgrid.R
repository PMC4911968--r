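#' Voxel grids, masks, planar images
#'
#' `voxel_grid` is the 3D scalar-field currency of the package: a numeric
#' array plus voxel spacing in mm. The axis convention is fixed throughout:
#' axis 1 = left-right (x), axis 2 = anterior-posterior (y, anterior at
#' index 1), axis 3 = caudal-cranial (z). All planar projections are along
#' axis 2.
#'
#' @param data numeric 3D array (counts, HU, or attenuation coefficient).
#' @param spacing numeric length-3, voxel spacing in mm (> 0).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)")
  structure(list(data = data, spacing = spacing), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid %dx%dx%d @ (%.3g, %.3g, %.3g) mm; range [%.4g, %.4g]>\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname voxel_grid
#' @param x a `voxel_grid`
#' @export
voxel_volume_ml <- function(x) prod(x$spacing) / 1000

#' Binary 3D mask on a voxel grid
#'
#' @param voxels logical 3D array.
#' @param spacing voxel spacing in mm.
#' @param label name of the structure the mask delineates.
#' @return An object of class `mask3d`.
#' @export
mask3d <- function(voxels, spacing, label = "mask") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (!is.logical(voxels)) {
    if (!all(voxels %in% c(0, 1))) stop("mask must be binary")
    voxels <- array(as.logical(voxels), dim(voxels))
  }
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 label = as.character(label)), class = "mask3d")
}

#' @export
print.mask3d <- function(x, ...) {
  cat(sprintf("<mask3d '%s': %d voxels on (%.1f ml)>\n", x$label,
              sum(x$voxels), sum(x$voxels) * prod(x$spacing) / 1000))
  invisible(x)
}

#' Binary region of interest on the (x, z) projection plane
#'
#' @param pixels logical matrix, rows = x, cols = z.
#' @param pixel_spacing numeric length-2, (x, z) pixel spacing in mm.
#' @param label ROI name (e.g. "kidney", "B1", ..., "B11").
#' @return An object of class `roi2d`.
#' @export
roi2d <- function(pixels, pixel_spacing, label = "roi") {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (!is.logical(pixels)) pixels <- matrix(as.logical(pixels), nrow(pixels))
  structure(list(pixels = pixels, pixel_spacing = as.numeric(pixel_spacing),
                 label = as.character(label)), class = "roi2d")
}

#' Planar projection image
#'
#' A 2D count image on the (x, z) plane as seen by an anterior or posterior
#' detector.
#'
#' @param counts numeric matrix, rows = x, cols = z.
#' @param pixel_spacing numeric length-2, (x, z) pixel spacing in mm.
#' @param view "anterior" or "posterior".
#' @return An object of class `planar_image`.
#' @export
planar_image <- function(counts, pixel_spacing, view = c("anterior", "posterior")) {
  view <- match.arg(view)
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  structure(list(counts = counts, pixel_spacing = as.numeric(pixel_spacing),
                 view = view), class = "planar_image")
}

# shared internal validators -------------------------------------------------

stopifnot_same_grid <- function(a, b) {
  da <- if (inherits(a, "voxel_grid")) dim(a$data) else dim(a$voxels)
  db <- if (inherits(b, "voxel_grid")) dim(b$data) else dim(b$voxels)
  sa <- a$spacing; sb <- b$spacing
  if (!identical(da, db) || max(abs(sa - sb)) > 1e-6)
    stop("grids do not match (shape or spacing)")
  invisible(TRUE)
}
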