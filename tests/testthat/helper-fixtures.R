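# Shared fixtures and independent oracles.

# Independent brute-force attenuated projector: per-voxel ray walk, nothing
# shared with attenuated_project() beyond the declared convention.
project_brute <- function(activity, mu, view) {
  d <- dim(activity$data)
  dy <- activity$spacing[2] / 10
  out <- matrix(0, d[1], d[3])
  for (x in seq_len(d[1])) for (z in seq_len(d[3])) {
    for (i in seq_len(d[2])) {
      nearer <- if (view == "anterior") seq_len(i - 1L) else
        if (i < d[2]) (i + 1L):d[2] else integer(0)
      path <- sum(mu[x, nearer, z]) * dy + 0.5 * mu[x, i, z] * dy
      out[x, z] <- out[x, z] + activity$data[x, i, z] * exp(-path)
    }
  }
  out
}

# small uniform-body phantom: box body filling most of the grid
box_body_spec <- function(grid = c(16L, 16L, 12L), spacing = c(10, 10, 10),
                          bg_ac = 1, hu = 0) {
  extent <- grid * spacing
  organ_spec("body", "box", extent / 2, extent * 0.45, bg_ac, hu)
}

# phantom with one ellipsoidal kidney inside a uniform box body
kidney_in_box_phantom <- function(kidney_ac = 10, bg_ac = 1,
                                  grid = c(40L, 40L, 24L),
                                  spacing = c(2.21, 2.21, 4.42),
                                  kid_semi = c(33, 33, 33), ...) {
  extent <- grid * spacing
  body <- organ_spec("body", "box", extent / 2, extent / 2 * 0.98, bg_ac, 0)
  kid <- organ_spec("kidney", "ellipsoid", extent / 2, kid_semi, kidney_ac, 30)
  build_phantom(phantom_spec(body, list(kid), grid_shape = grid,
                             voxel_spacing = spacing, ...))
}

# reference-BFS largest component (independent of the RLE labeller)
largest_component_bfs <- function(on) {
  idx <- which(on)
  visited <- logical(length(on))
  best <- integer(0)
  for (i in idx) if (!visited[i]) {
    r <- conjview:::flood6(on, i, visited)
    visited <- r$visited
    if (length(r$member) > length(best)) best <- r$member
  }
  out <- array(FALSE, dim(on)); out[best] <- TRUE
  out
}

make_geometry <- function(t_k, t_p, d_k, v_k) {
  structure(list(t_k = t_k, t_p = t_p, d_k = d_k, v_k = v_k),
            class = "kidney_geometry")
}
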