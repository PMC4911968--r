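#' Total counts inside a planar ROI
#'
#' @param img a `planar_image`.
#' @param roi an `roi2d` on the same plane.
#' @return Sum of pixel counts inside the ROI.
#' @export
roi_counts <- function(img, roi) {
  stopifnot(inherits(img, "planar_image"), inherits(roi, "roi2d"))
  if (!identical(dim(img$counts), dim(roi$pixels)))
    stop("planar image and ROI shapes differ")
  sum(img$counts[roi$pixels])
}

#' Mean concentration inside a VOI
#'
#' The SPECT-style volumetric reference: mean voxel counts in the mask
#' divided by the voxel volume.
#'
#' @param vol a `voxel_grid` of counts.
#' @param m a non-empty `mask3d` on the same grid.
#' @return Concentration in counts/ml.
#' @export
voi_mean_concentration <- function(vol, m) {
  stopifnot(inherits(vol, "voxel_grid"), inherits(m, "mask3d"))
  stopifnot_same_grid(vol, m)
  if (!any(m$voxels)) stop("empty mask")
  mean(vol$data[m$voxels]) / voxel_volume_ml(vol)
}

#' Background scaling factor for net-count subtraction
#'
#' Scales the raw background-ROI counts so that the subtracted background
#' resembles the over- and underlying tissue volume of the kidney column:
#' (kidney column voxels - kidney voxels) / background column voxels.
#'
#' @param kidney_column kidney column `mask3d`.
#' @param kidney kidney `mask3d` (subset of the column).
#' @param bg_column non-empty background column `mask3d`.
#' @return The scale ratio.
#' @export
background_scale_factor <- function(kidney_column, kidney, bg_column) {
  stopifnot(inherits(kidney_column, "mask3d"), inherits(kidney, "mask3d"),
            inherits(bg_column, "mask3d"))
  if (any(kidney$voxels & !kidney_column$voxels))
    stop("kidney VOI is not contained in its column VOI")
  nb <- sum(bg_column$voxels)
  if (nb == 0) stop("empty background column VOI")
  (sum(kidney_column$voxels) - sum(kidney$voxels)) / nb
}

#' Background-subtracted net counts with negativity flags
#'
#' A_net and P_net are the kidney ROI counts minus the scaled background ROI
#' counts in the anterior and posterior views. Negative nets are recorded as
#' data, not errors: the conjugate-view method is invalid when A_net and/or
#' P_net <= 0, the posterior-view method when P_net <= 0.
#'
#' @param kidney_counts_a,kidney_counts_p kidney ROI counts (anterior/posterior).
#' @param bg_counts_a,bg_counts_p raw background ROI counts.
#' @param scale background scaling factor (see [background_scale_factor()]).
#' @param bg_label name of the background ROI.
#' @return A list of class `net_count_result`.
#' @export
net_counts <- function(kidney_counts_a, kidney_counts_p,
                       bg_counts_a, bg_counts_p, scale, bg_label = "bg") {
  if (min(kidney_counts_a, kidney_counts_p, bg_counts_a, bg_counts_p) < 0)
    stop("raw ROI counts must be >= 0")
  if (scale < 0) stop("scale must be >= 0")
  a_net <- kidney_counts_a - scale * bg_counts_a
  p_net <- kidney_counts_p - scale * bg_counts_p
  structure(list(a_net = a_net, p_net = p_net, bg_label = bg_label,
                 conjv_negative = (a_net <= 0 || p_net <= 0),
                 postv_negative = (p_net <= 0)),
            class = "net_count_result")
}

# shared guard for the two planar estimators
check_geometry <- function(g, mu) {
  stopifnot(inherits(g, "kidney_geometry"))
  if (!is.finite(mu) || mu < 0) stop("mu must be >= 0")
  if (g$v_k <= 0) stop("kidney volume must be positive")
}

#' Conjugate-view activity concentration
#'
#' The geometric-mean estimator
#' AC = mu * t_k * sqrt(A_net * P_net) /
#'      (exp(-mu * t_p / 2) * (exp(mu * t_k / 2) - exp(-mu * t_k / 2)) * v_k),
#' with the exact mu -> 0 limit sqrt(A_net * P_net) * exp(mu * t_p / 2) / v_k
#' used when mu * t_k < 1e-8 for numerical stability.
#'
#' @param nc a `net_count_result` with `conjv_negative = FALSE`.
#' @param g a `kidney_geometry`.
#' @param mu effective attenuation coefficient in 1/cm (scalar, >= 0).
#' @return A list of class `ac_estimate` (value in counts/ml, method "ConjV").
#' @export
ac_conjv <- function(nc, g, mu) {
  stopifnot(inherits(nc, "net_count_result"))
  check_geometry(g, mu)
  if (nc$conjv_negative)
    stop("negative net counts: conjugate-view estimate refused")
  gm <- sqrt(nc$a_net * nc$p_net)
  value <- if (mu * g$t_k < 1e-8) {
    gm * exp(mu * g$t_p / 2) / g$v_k
  } else {
    mu * g$t_k * gm /
      (exp(-mu * g$t_p / 2) * (exp(mu * g$t_k / 2) - exp(-mu * g$t_k / 2)) * g$v_k)
  }
  structure(list(value = value, method = "ConjV", bg_label = nc$bg_label),
            class = "ac_estimate")
}

#' Posterior-view activity concentration
#'
#' The single-view estimator
#' AC = (P_net / v_k) * exp(mu * d_k) * t_k * mu / (1 - exp(-mu * t_k)),
#' with the exact mu -> 0 limit P_net * exp(mu * d_k) / v_k used when
#' mu * t_k < 1e-8.
#'
#' @inheritParams ac_conjv
#' @param nc a `net_count_result` with `postv_negative = FALSE`.
#' @return A list of class `ac_estimate` (value in counts/ml, method "PostV").
#' @export
ac_postv <- function(nc, g, mu) {
  stopifnot(inherits(nc, "net_count_result"))
  check_geometry(g, mu)
  if (nc$postv_negative)
    stop("negative net counts: posterior-view estimate refused")
  value <- if (mu * g$t_k < 1e-8) {
    nc$p_net * exp(mu * g$d_k) / g$v_k
  } else {
    (nc$p_net / g$v_k) * exp(mu * g$d_k) * g$t_k * mu / (1 - exp(-mu * g$t_k))
  }
  structure(list(value = value, method = "PostV", bg_label = nc$bg_label),
            class = "ac_estimate")
}
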