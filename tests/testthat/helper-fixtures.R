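# Shared fixtures: analytic polylines and flat ribbon meshes with known
# geometry, so expectations can be written against closed-form answers.

# Flat rectangular grid mesh at height z; triangle winding gives outward
# normals along +z (so "above the mesh" has positive signed distance).
flat_mesh <- function(z = 0, role = "white", xr = c(-20, 20), yr = c(0, 20),
                      step = 2) {
  xs <- seq(xr[1], xr[2], by = step)
  ys <- seq(yr[1], yr[2], by = step)
  nx <- length(xs)
  ny <- length(ys)
  v <- cbind(rep(xs, ny), rep(ys, each = nx), z)
  idx <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  f <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
             cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  surface_mesh(v, f, role = role)
}

# Half circle of radius r in the x-y plane, from (r,0,0) to (-r,0,0).
semicircle_streamline <- function(r = 1, n = 181) {
  th <- seq(0, pi, length.out = n)
  streamline(cbind(r * cos(th), r * sin(th), 0))
}

# Symmetric V with interior apex angle theta at the origin, arms opening
# towards +y; the angle between the apex-to-endpoint vectors is theta.
v_polyline <- function(theta_deg, arm = 10, step = 0.1) {
  phi <- theta_deg / 2 * pi / 180
  sl <- seq(arm, 0, by = -step)
  sr <- seq(step, arm, by = step)
  streamline(rbind(cbind(-sl * sin(phi), sl * cos(phi), 0),
                   cbind(sr * sin(phi), sr * cos(phi), 0)))
}

straight_streamline <- function(len = 10, step = 0.5) {
  streamline(cbind(seq(0, len, by = step), 0, 0))
}

# Vertical segment at (x, y) spanning z in [z1, z2].
vertical_streamline <- function(x, y, z1, z2, n = 25) {
  streamline(cbind(x, y, seq(z1, z2, length.out = n)))
}

# Surface V1/V2 labels on a flat (or phantom) mesh, split at x = 0.
split_labels <- function(mesh) {
  vx <- mesh$vertices[, 1]
  list(v1 = cortical_label("V1", vertices = which(vx < 0)),
       v2 = cortical_label("V2", vertices = which(vx >= 0)))
}
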