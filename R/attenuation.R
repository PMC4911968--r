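#' Convert a CT Hounsfield volume to a linear attenuation map
#'
#' Uses the linear rescaling mu = mu_w + HU * mu_w / 1000, with mu_w the
#' effective linear attenuation coefficient of water for the 208 keV photons
#' of 177Lu. Values are clamped below at zero (air voxels can round slightly
#' negative).
#'
#' @param hu a `voxel_grid` of Hounsfield values.
#' @param mu_w effective water attenuation coefficient in 1/cm (> 0).
#'   Default 0.136 1/cm (narrow-beam water at 208 keV); always overridable.
#' @return A list of class `attenuation_map` with `mu` (`voxel_grid`, 1/cm)
#'   and `mu_w`.
#' @export
hu_to_mu <- function(hu, mu_w = 0.136) {
  stopifnot(inherits(hu, "voxel_grid"))
  if (!is.finite(mu_w) || mu_w <= 0) stop("mu_w must be > 0")
  if (any(!is.finite(hu$data))) stop("HU volume contains non-finite values")
  mu <- mu_w + hu$data * mu_w / 1000
  mu[mu < 0] <- 0
  structure(list(mu = voxel_grid(mu, hu$spacing), mu_w = mu_w),
            class = "attenuation_map")
}

#' Attenuated planar projection of an activity volume
#'
#' Forms the anterior or posterior planar image by summing each
#' anterior-posterior column of the activity volume with exponential
#' attenuation: voxel i contributes a_i * exp(-(sum of mu over voxels nearer
#' the detector + mu_i / 2) * dy), where dy is the voxel size along the AP
#' axis in cm. The half-voxel self-attenuation term makes the discrete sum
#' converge to the continuous slab integral. "Nearer the detector" means
#' smaller y index for the anterior view and larger y index for the
#' posterior view.
#'
#' @param activity a `voxel_grid` of counts.
#' @param att an `attenuation_map` on the same grid (or NULL for mu = 0).
#' @param view "anterior" or "posterior".
#' @return A `planar_image` on the (x, z) plane.
#' @export
attenuated_project <- function(activity, att = NULL,
                               view = c("anterior", "posterior")) {
  view <- match.arg(view)
  stopifnot(inherits(activity, "voxel_grid"))
  d <- dim(activity$data)
  if (is.null(att)) {
    mu <- array(0, d)
  } else {
    stopifnot(inherits(att, "attenuation_map"))
    stopifnot_same_grid(activity, att$mu)
    mu <- att$mu$data
  }
  dy_cm <- activity$spacing[2] / 10
  ys <- if (view == "anterior") seq_len(d[2]) else rev(seq_len(d[2]))

  img <- matrix(0, d[1], d[3])
  path <- matrix(0, d[1], d[3])          # cumulative mu*dy nearer the detector
  for (iy in ys) {
    m <- mu[, iy, , drop = TRUE] * dy_cm
    img <- img + activity$data[, iy, , drop = TRUE] * exp(-(path + 0.5 * m))
    path <- path + m
  }
  planar_image(img, activity$spacing[c(1, 3)], view)
}
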