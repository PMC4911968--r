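# Connected-component utilities (6-connectivity, vectorised frontier BFS).
# Linear indices; x varies fastest, then y, then z.

flood6 <- function(on, start, visited = logical(length(on))) {
  d <- dim(on); nx <- d[1]; nxy <- d[1] * d[2]; n <- prod(d)
  frontier <- start[on[start] & !visited[start]]
  visited[frontier] <- TRUE
  member <- frontier
  while (length(frontier)) {
    i0 <- frontier - 1L
    x <- i0 %% nx
    y <- (i0 %/% nx) %% d[2]
    z <- i0 %/% nxy
    cand <- c(frontier[x > 0L] - 1L, frontier[x < nx - 1L] + 1L,
              frontier[y > 0L] - nx, frontier[y < d[2] - 1L] + nx,
              frontier[z > 0L] - nxy, frontier[z < d[3] - 1L] + nxy)
    cand <- unique(cand[on[cand] & !visited[cand]])
    visited[cand] <- TRUE
    member <- c(member, cand)
    frontier <- cand
  }
  list(member = member, visited = visited)
}

# Largest 6-connected component via run-length encoding along x and a
# union-find over run overlaps between adjacent AP/axial columns. Orders of
# magnitude faster than voxel-wise BFS on SPECT-sized grids.
largest_component6 <- function(on) {
  d <- dim(on); nx <- d[1]; ncol3 <- d[2] * d[3]
  v <- as.logical(on)
  n <- length(v)
  xpos <- rep.int(seq_len(nx), ncol3)
  prev <- c(FALSE, v[-n])
  nxt <- c(v[-1], FALSE)
  si <- which(v & (!prev | xpos == 1L))
  if (!length(si)) return(array(FALSE, d))
  ei <- which(v & (!nxt | xpos == nx))
  len <- ei - si + 1L
  cid <- (si - 1L) %/% nx              # 0-based (y, z) column id
  xs <- (si - 1L) %% nx
  xe <- xs + len - 1L
  y <- cid %% d[2]; z <- cid %/% d[2]

  parent <- seq_along(si)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  dt <- data.table::data.table(cid = cid, xs = xs, xe = xe, run = seq_along(si))
  data.table::setkey(dt, cid, xs, xe)
  for (step in c(1L, d[2])) {                 # y+1 and z+1 neighbours
    ok <- if (step == 1L) y < d[2] - 1L else z < d[3] - 1L
    if (!any(ok)) next
    qry <- data.table::data.table(cid = cid[ok] + step, xs = xs[ok],
                                  xe = xe[ok], run = which(ok))
    hits <- data.table::foverlaps(qry, dt, type = "any", nomatch = NULL)
    if (nrow(hits)) for (j in seq_len(nrow(hits))) {
      a <- find(hits$run[j]); b <- find(hits$i.run[j])
      if (a != b) parent[b] <- a
    }
  }
  root <- vapply(seq_along(si), find, 1L)
  sizes <- rowsum(len, root)
  best <- as.integer(rownames(sizes))[which.max(sizes)]
  sel <- root == best
  out <- array(FALSE, d)
  out[sequence(len[sel], from = si[sel])] <- TRUE
  out
}

#' Segment the patient body from the surrounding air
#'
#' Thresholds the count volume (default 5 counts, the level used to separate
#' body from air), keeps the largest 6-connected component, and fills holes
#' along each anterior-posterior column so that backprojected column VOIs
#' span the full body thickness.
#'
#' @param counts a `voxel_grid` of counts (>= 0).
#' @param threshold minimum counts for a voxel to be considered body.
#' @return A `mask3d` labelled "body".
#' @export
body_mask <- function(counts, threshold = 5) {
  stopifnot(inherits(counts, "voxel_grid"))
  if (any(counts$data < 0)) stop("counts must be >= 0")
  on <- counts$data >= threshold
  if (!any(on)) stop("no voxel reaches the body threshold")
  on <- largest_component6(on)
  # fill along AP columns: body occupies [ymin, ymax] in every occupied column
  d <- dim(on)
  idx <- which(on, arr.ind = TRUE)
  key <- idx[, 1] + (idx[, 3] - 1L) * d[1]
  yr <- vapply(split(idx[, 2], key), range, integer(2))
  keys <- as.integer(colnames(yr))
  xk <- ((keys - 1L) %% d[1]) + 1L
  zk <- ((keys - 1L) %/% d[1]) + 1L
  for (j in seq_along(keys)) on[xk[j], yr[1, j]:yr[2, j], zk[j]] <- TRUE
  mask3d(on, counts$spacing, "body")
}

#' Segment a kidney by fraction-of-maximum region growing
#'
#' Thresholds at `frac` times the maximum count found within a probe sphere
#' around the seed point and keeps the 6-connected component containing the
#' seed. This is a stand-in for an unspecified clinical segmentation
#' algorithm; on phantoms the ground-truth organ mask can be used instead.
#'
#' @param counts a `voxel_grid`.
#' @param seed_point integer length-3 voxel index inside the kidney.
#' @param frac threshold as a fraction of the probe maximum (0 < frac <= 1).
#' @param probe_radius_cm radius of the seed-centred probe sphere.
#' @param min_volume_ml segments smaller than this are rejected as degenerate.
#' @return A `mask3d` labelled "kidney".
#' @export
segment_kidney <- function(counts, seed_point, frac = 0.5,
                           probe_radius_cm = 5, min_volume_ml = 20) {
  stopifnot(inherits(counts, "voxel_grid"))
  d <- dim(counts$data)
  seed_point <- as.integer(seed_point)
  if (length(seed_point) != 3L || any(seed_point < 1L) || any(seed_point > d))
    stop("seed_point outside the grid")
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  sp <- counts$spacing
  ctr <- (seed_point - 0.5) * sp
  q1 <- (((seq_len(d[1]) - 0.5) * sp[1] - ctr[1]) / (probe_radius_cm * 10))^2
  q2 <- (((seq_len(d[2]) - 0.5) * sp[2] - ctr[2]) / (probe_radius_cm * 10))^2
  q3 <- (((seq_len(d[3]) - 0.5) * sp[3] - ctr[3]) / (probe_radius_cm * 10))^2
  probe <- outer(outer(q1, q2, `+`), q3, `+`) <= 1
  thr <- frac * max(counts$data[probe])
  on <- counts$data >= thr
  lin <- seed_point[1] + (seed_point[2] - 1L) * d[1] +
    (seed_point[3] - 1L) * d[1] * d[2]
  if (!on[lin]) stop("seed point is below the segmentation threshold")
  member <- flood6(on, lin)$member
  if (length(member) * prod(sp) / 1000 < min_volume_ml)
    stop("segment below minimum kidney volume; seed likely in background")
  out <- array(FALSE, d); out[member] <- TRUE
  mask3d(out, sp, "kidney")
}

#' Project a 3D mask onto the (x, z) plane
#'
#' A pixel is on iff any voxel along its anterior-posterior column is on.
#'
#' @param m a non-empty `mask3d`.
#' @return An `roi2d` with the mask's label.
#' @export
project_mask_to_roi <- function(m) {
  stopifnot(inherits(m, "mask3d"))
  if (!any(m$voxels)) stop("cannot project an empty mask")
  roi2d(apply(m$voxels, c(1, 3), any), m$spacing[c(1, 3)], m$label)
}

#' Backproject a planar ROI into a body-clipped column VOI
#'
#' Every voxel whose (x, z) pixel lies in the ROI and which lies inside the
#' body mask is included, so each column's length equals the local body
#' thickness (anterior to posterior surface).
#'
#' @param roi an `roi2d`.
#' @param body a `mask3d` for the body.
#' @return A `mask3d` labelled `<roi label>_column`.
#' @export
backproject_roi_to_column <- function(roi, body) {
  stopifnot(inherits(roi, "roi2d"), inherits(body, "mask3d"))
  d <- dim(body$voxels)
  if (!identical(dim(roi$pixels), d[c(1, 3)]))
    stop("ROI plane does not match the body grid")
  roi3 <- aperm(array(roi$pixels, c(d[1], d[3], d[2])), c(1, 3, 2))
  col <- roi3 & body$voxels
  if (!any(col)) stop("ROI lies entirely outside the body silhouette")
  mask3d(col, body$spacing, paste0(roi$label, "_column"))
}

#' True background VOI: column minus kidney
#'
#' The over- and underlying tissue compartment, obtained by subtracting the
#' kidney VOI from its body-clipped column VOI.
#'
#' @param column the kidney column `mask3d`.
#' @param kidney the kidney `mask3d` (must be a subset of `column`).
#' @return A `mask3d` labelled "TB". Empty TB (kidney fills its whole
#'   column) is flagged with a warning and attribute `degenerate`.
#' @export
true_background_voi <- function(column, kidney) {
  stopifnot(inherits(column, "mask3d"), inherits(kidney, "mask3d"))
  stopifnot_same_grid(column, kidney)
  if (any(kidney$voxels & !column$voxels))
    stop("kidney VOI is not contained in the column VOI")
  tb <- mask3d(column$voxels & !kidney$voxels, column$spacing, "TB")
  if (!any(tb$voxels)) {
    warning("true background VOI is empty (kidney fills its column)")
    attr(tb, "degenerate") <- TRUE
  }
  tb
}

#' Build the sector background ROIs B1..Bn and the surrounding ROI
#'
#' A band at Euclidean distance (`gap`, `gap + width`] pixels from the kidney
#' ROI is split into `n_sectors` angular sectors about the kidney-ROI
#' centroid. Angle 0 points cranial (+z) and increases towards the patient's
#' left (+x); sector k collects pixels with angle in [(k-1), k) * 360 / n.
#' The surrounding ROI (B11 for 10 sectors) is the whole band, so the
#' sectors partition it exactly.
#'
#' @param kidney_roi a non-empty `roi2d`.
#' @param gap distance in pixels between kidney ROI and band (default 2).
#' @param width band width in pixels (default 4).
#' @param n_sectors number of angular sectors (default 10).
#' @return Named list of `roi2d`: B1..Bn plus the surrounding band B<n+1>.
#' @export
build_background_rois <- function(kidney_roi, gap = 2, width = 4, n_sectors = 10) {
  stopifnot(inherits(kidney_roi, "roi2d"))
  px <- kidney_roi$pixels
  if (!any(px)) stop("kidney ROI is empty")
  if (gap < 0 || width <= 0 || n_sectors < 1) stop("invalid band parameters")
  d <- dim(px)
  idx <- which(px, arr.ind = TRUE)
  r <- gap + width
  if (min(idx[, 1]) - r < 1 || max(idx[, 1]) + r > d[1] ||
      min(idx[, 2]) - r < 1 || max(idx[, 2]) + r > d[2])
    stop("kidney ROI too close to the image edge for the background band")

  cx <- seq(max(1, min(idx[, 1]) - ceiling(r)), min(d[1], max(idx[, 1]) + ceiling(r)))
  cz <- seq(max(1, min(idx[, 2]) - ceiling(r)), min(d[2], max(idx[, 2]) + ceiling(r)))
  cand <- as.matrix(expand.grid(x = cx, z = cz))
  # Euclidean distance transform to the ROI pixel set (brute force on the
  # bounding box; band candidates number a few thousand at SPECT matrix sizes)
  d2 <- outer(cand[, 1], idx[, 1], `-`)^2 + outer(cand[, 2], idx[, 2], `-`)^2
  mind <- sqrt(do.call(pmin, as.data.frame(d2)))
  band <- cand[mind > gap & mind <= gap + width, , drop = FALSE]
  if (!nrow(band)) stop("background band is empty")

  ctr <- colMeans(idx)                       # real-valued centroid, no rounding
  ang <- atan2(band[, 1] - ctr[1], band[, 2] - ctr[2]) * 180 / pi
  ang <- ang %% 360
  sector <- pmin(floor(ang / (360 / n_sectors)) + 1L, n_sectors)

  mk <- function(rows, label) {
    m <- matrix(FALSE, d[1], d[2])
    m[rows] <- TRUE
    roi2d(m, kidney_roi$pixel_spacing, label)
  }
  out <- lapply(seq_len(n_sectors), function(k)
    mk(band[sector == k, , drop = FALSE], paste0("B", k)))
  names(out) <- paste0("B", seq_len(n_sectors))
  out[[paste0("B", n_sectors + 1L)]] <- mk(band, paste0("B", n_sectors + 1L))
  out
}

#' Kidney geometry for the conjugate-view and posterior-view formulas
#'
#' On the transverse slice through the kidney centroid, along the AP line
#' through the kidney's in-slice centroid: t_k is the kidney AP extent, t_p
#' the body AP extent, and d_k the distance from the posterior body surface
#' to the posterior kidney surface (all cm). v_k is the kidney volume from
#' its full 3D mask (ml).
#'
#' @param kidney kidney `mask3d`.
#' @param body body `mask3d` on the same grid.
#' @return A list of class `kidney_geometry` with t_k, t_p, d_k (cm), v_k (ml).
#' @export
measure_geometry <- function(kidney, body) {
  stopifnot(inherits(kidney, "mask3d"), inherits(body, "mask3d"))
  stopifnot_same_grid(kidney, body)
  if (!any(kidney$voxels)) stop("empty kidney mask")
  if (any(kidney$voxels & !body$voxels)) stop("kidney extends outside the body")
  sp <- kidney$spacing
  idx <- which(kidney$voxels, arr.ind = TRUE)
  z0 <- round(mean(idx[, 3]))
  in_slice <- idx[idx[, 3] == z0, , drop = FALSE]
  if (!nrow(in_slice)) stop("kidney absent from its centroid slice")
  x0 <- round(mean(in_slice[, 1]))
  ky <- which(kidney$voxels[x0, , z0])
  by <- which(body$voxels[x0, , z0])
  if (!length(ky) || !length(by)) stop("kidney absent from its centroid AP line")
  dy_cm <- sp[2] / 10
  g <- list(
    t_k = (max(ky) - min(ky) + 1L) * dy_cm,
    t_p = (max(by) - min(by) + 1L) * dy_cm,
    d_k = (max(by) - max(ky)) * dy_cm,      # posterior = larger y index
    v_k = nrow(idx) * prod(sp) / 1000)
  if (g$t_k >= g$t_p) stop("kidney spans the whole body thickness")
  if (g$d_k < 0) stop("kidney posterior surface behind the body surface")
  structure(g, class = "kidney_geometry")
}

#' @export
print.kidney_geometry <- function(x, ...) {
  cat(sprintf("<kidney_geometry t_k=%.2f cm t_p=%.2f cm d_k=%.2f cm v_k=%.1f ml>\n",
              x$t_k, x$t_p, x$d_k, x$v_k))
  invisible(x)
}
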