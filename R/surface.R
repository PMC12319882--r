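#' Triangulated cortical surface meshes
#'
#' A surface mesh holds vertex positions in world millimetres (RAS) and a
#' triangle index matrix, tagged with its anatomical role (`"white"` for the
#' grey/white boundary, `"pial"` for the grey/CSF boundary).  Construction
#' validates that triangle indices are in range, that no triangle is
#' degenerate (zero area), and that triangle winding is consistent: every
#' edge shared by two triangles is traversed in opposite directions, so the
#' mesh is orientable and its triangle normals define a coherent
#' outside.  For white surfaces the convention throughout the package is
#' that normals point outward, away from the white matter and towards the
#' pial surface.
#'
#' @param vertices numeric V x 3 matrix of positions (mm).
#' @param triangles integer F x 3 matrix of vertex indices (1-based).
#' @param role `"white"` or `"pial"`.
#' @return a `"surface_mesh"` object.
#' @export
surface_mesh <- function(vertices, triangles, role = c("white", "pial")) {
  role <- match.arg(role)
  v <- as_points3(vertices, "vertices")
  f <- as.matrix(triangles)
  if (ncol(f) != 3) abort("triangles must be an F x 3 index matrix")
  storage.mode(f) <- "integer"
  if (any(f < 1L) || any(f > nrow(v))) abort("triangle indices out of range")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])) {
    abort("triangle with repeated vertex indices")
  }
  areas <- triangle_areas(v, f)
  if (any(areas < 1e-12)) abort("degenerate (zero-area) triangle in mesh")
  check_winding(f)
  structure(list(vertices = v, triangles = f, role = role),
            class = "surface_mesh")
}

triangle_areas <- function(v, f) {
  ab <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  ac <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  0.5 * row_norms(cr)
}

# every directed edge may appear at most once, and an undirected edge at
# most twice -- i.e. shared edges are traversed in opposite directions
check_winding <- function(f) {
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key_dir <- paste(e[, 1], e[, 2])
  if (anyDuplicated(key_dir)) abort("inconsistent triangle winding (repeated directed edge)")
  key_und <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (any(table(key_und) > 2)) abort("non-manifold edge (shared by > 2 triangles)")
  invisible(TRUE)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh role=%s> %d vertices, %d triangles\n",
              x$role, nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Per-vertex 1-ring adjacency
#'
#' @param mesh a [surface_mesh()].
#' @return list of integer vectors; element `i` holds the vertices sharing
#'   an edge with vertex `i` (excluding `i` itself).
#' @export
vertex_adjacency <- function(mesh) {
  f <- mesh$triangles
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  adj <- split(e[, 2], factor(e[, 1], levels = seq_len(n_vertices(mesh))))
  lapply(adj, function(x) sort(unique(x)))
}

# area-weighted vertex normals (unit length); follow triangle winding
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$triangles
  ab <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  ac <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  n <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    for (k in 1:3) {
      acc <- rowsum(cr[, k], group = f[, j])
      idx <- as.integer(rownames(acc))
      n[idx, k] <- n[idx, k] + acc[, 1]
    }
  }
  len <- row_norms(n)
  len[len == 0] <- 1
  n / len
}

# ---- scalar maps ---------------------------------------------------------

#' Per-vertex scalar maps
#'
#' Carries one scalar per mesh vertex plus a kind tag that fixes units and
#' admissible range: eccentricity (degrees of visual angle, >= 0), polar
#' angle (degrees, circular on [0, 360); out-of-range values are wrapped on
#' construction with a warning), or SNR (unitless, >= 0).  A per-vertex
#' `valid` flag marks vertices that carry a value; smoothed maps leave
#' unreliable vertices unvalued (`NA`, `valid = FALSE`).
#'
#' @param values numeric vector, one value per vertex (`NA` allowed where
#'   `valid` is `FALSE`).
#' @param kind `"eccentricity"`, `"polar_angle"` or `"snr"`.
#' @param valid logical vector; defaults to `!is.na(values)`.
#' @return a `"vertex_scalar_map"` object.
#' @export
vertex_scalar_map <- function(values,
                              kind = c("eccentricity", "polar_angle", "snr"),
                              valid = NULL) {
  kind <- match.arg(kind)
  values <- as.double(values)
  if (is.null(valid)) valid <- !is.na(values)
  valid <- as.logical(valid)
  if (length(valid) != length(values)) abort("valid flags must match values in length")
  if (any(valid & is.na(values))) abort("valid vertex with missing value")
  v_ok <- values[valid]
  if (kind == "polar_angle" && length(v_ok) && any(v_ok < 0 | v_ok >= 360)) {
    warn("polar angle values outside [0, 360) wrapped into the principal interval")
    values[valid] <- wrap_degrees(values[valid])
  }
  if (kind %in% c("eccentricity", "snr") && length(v_ok) && any(v_ok < 0)) {
    abort(sprintf("%s values must be non-negative", kind))
  }
  structure(list(values = values, kind = kind, valid = valid),
            class = "vertex_scalar_map")
}

#' @export
print.vertex_scalar_map <- function(x, ...) {
  cat(sprintf("<vertex_scalar_map kind=%s> %d vertices (%d valid)\n",
              x$kind, length(x$values), sum(x$valid)))
  invisible(x)
}

#' @export
length.vertex_scalar_map <- function(x) length(x$values)

# ---- plain-text carriers -------------------------------------------------
# OFF-style meshes and one-value-per-line scalar maps: the package's
# documented plain-text surface format.

#' Read / write surface meshes as OFF text files
#'
#' Standard Object File Format: an `OFF` magic line, a `V F E` count line,
#' `V` vertex coordinate lines, then `F` face lines `3 i j k` with 0-based
#' indices.
#'
#' @param path file path.
#' @param role anatomical role to tag the mesh with on read.
#' @return `read_surface_off()` returns a [surface_mesh()].
#' @export
read_surface_off <- function(path, role = c("white", "pial")) {
  role <- match.arg(role)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!identical(trimws(lines[1]), "OFF")) abort(sprintf("not an OFF file: %s", path))
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  vals <- scan(text = lines[2 + seq_len(nv)], quiet = TRUE)
  v <- matrix(vals, ncol = 3, byrow = TRUE)
  fvals <- scan(text = lines[2 + nv + seq_len(nf)], quiet = TRUE)
  fm <- matrix(fvals, ncol = 4, byrow = TRUE)
  if (any(fm[, 1] != 3)) abort("only triangle faces are supported")
  surface_mesh(v, fm[, 2:4] + 1L, role = role)
}

#' @rdname read_surface_off
#' @param mesh a [surface_mesh()].
#' @export
write_surface_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; f <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("OFF", sprintf("%d %d 0", nrow(v), nrow(f))), con)
  writeLines(apply(v, 1, function(r) paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(f - 1L, 1, function(r) paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' Read / write per-vertex scalar maps as one-value-per-line text
#'
#' `NA` lines mark unvalued vertices.
#'
#' @param path file path.
#' @param kind map kind, see [vertex_scalar_map()].
#' @return `read_vertex_map()` returns a [vertex_scalar_map()].
#' @export
read_vertex_map <- function(path, kind) {
  vals <- suppressWarnings(as.double(readLines(path, warn = FALSE)))
  vertex_scalar_map(vals, kind = kind)
}

#' @rdname read_vertex_map
#' @param map a [vertex_scalar_map()].
#' @export
write_vertex_map <- function(map, path) {
  stopifnot(inherits(map, "vertex_scalar_map"))
  out <- ifelse(map$valid, format(map$values, digits = 17), "NA")
  writeLines(out, path)
  invisible(path)
}

#' Read a surface mesh together with its scalar maps
#'
#' Binds a mesh and any number of per-vertex maps, rejecting maps whose
#' vertex count does not match the mesh.
#'
#' @param surf_path OFF mesh path.
#' @param ... named map paths; names give the map kinds (e.g.
#'   `eccentricity = "ecc.txt"`).
#' @param role mesh role.
#' @return list with elements `mesh` and `maps` (named list of
#'   [vertex_scalar_map()]).
#' @export
read_surface_and_maps <- function(surf_path, ..., role = c("white", "pial")) {
  mesh <- read_surface_off(surf_path, role = role)
  paths <- list(...)
  kinds <- names(paths)
  if (length(paths) && (is.null(kinds) || any(kinds == ""))) {
    abort("map paths must be named by their kind")
  }
  bad <- setdiff(kinds, c("eccentricity", "polar_angle", "snr"))
  if (length(bad)) abort(sprintf("unknown map kind(s): %s", paste(bad, collapse = ", ")))
  maps <- lapply(kinds, function(k) {
    m <- read_vertex_map(paths[[k]], kind = k)
    if (length(m) != n_vertices(mesh)) {
      abort(sprintf("map '%s' has %d values but mesh has %d vertices",
                    k, length(m), n_vertices(mesh)))
    }
    m
  })
  names(maps) <- kinds
  list(mesh = mesh, maps = maps)
}

# ---- closest-point queries ----------------------------------------------

# closest point on each of a set of triangles to a single point p
# (Ericson's region test, vectorised over triangles); returns the winning
# triangle, the closest point, squared distance, and barycentric weights
closest_on_triangles <- function(p, A, B, C) {
  ab <- B - A; ac <- C - A
  ap <- matrix(p, nrow(A), 3, byrow = TRUE) - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- matrix(p, nrow(A), 3, byrow = TRUE) - B
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- matrix(p, nrow(A), 3, byrow = TRUE) - C
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)

  P <- matrix(NA_real_, nrow(A), 3)
  done <- rep(FALSE, nrow(A))

  set_rows <- function(rows, pts) {
    P[rows, ] <<- pts
    done[rows] <<- TRUE
  }
  r <- !done & d1 <= 0 & d2 <= 0                      # vertex A
  if (any(r)) set_rows(r, A[r, , drop = FALSE])
  r <- !done & d3 >= 0 & d4 <= d3                     # vertex B
  if (any(r)) set_rows(r, B[r, , drop = FALSE])
  r <- !done & d6 >= 0 & d5 <= d6                     # vertex C
  if (any(r)) set_rows(r, C[r, , drop = FALSE])
  vc <- d1 * d4 - d3 * d2
  r <- !done & vc <= 0 & d1 >= 0 & d3 <= 0            # edge AB
  if (any(r)) {
    tt <- d1[r] / (d1[r] - d3[r])
    set_rows(r, A[r, , drop = FALSE] + tt * ab[r, , drop = FALSE])
  }
  vb <- d5 * d2 - d1 * d6
  r <- !done & vb <= 0 & d2 >= 0 & d6 <= 0            # edge AC
  if (any(r)) {
    tt <- d2[r] / (d2[r] - d6[r])
    set_rows(r, A[r, , drop = FALSE] + tt * ac[r, , drop = FALSE])
  }
  va <- d3 * d6 - d5 * d4
  r <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0  # edge BC
  if (any(r)) {
    tt <- (d4[r] - d3[r]) / ((d4[r] - d3[r]) + (d5[r] - d6[r]))
    set_rows(r, B[r, , drop = FALSE] +
                  tt * (C[r, , drop = FALSE] - B[r, , drop = FALSE]))
  }
  r <- !done                                           # face interior
  if (any(r)) {
    denom <- 1 / (va[r] + vb[r] + vc[r])
    vv <- vb[r] * denom; ww <- vc[r] * denom
    set_rows(r, A[r, , drop = FALSE] + vv * ab[r, , drop = FALSE] +
                  ww * ac[r, , drop = FALSE])
  }
  d2p <- rowSums((P - matrix(p, nrow(A), 3, byrow = TRUE))^2)
  best <- which.min(d2p)
  # barycentric weights of the winning closest point
  a <- A[best, ]; b <- B[best, ]; cc <- C[best, ]; q <- P[best, ]
  v0 <- b - a; v1 <- cc - a; v2 <- q - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  w2 <- (d11 * d20 - d01 * d21) / den
  w3 <- (d00 * d21 - d01 * d20) / den
  bary <- c(1 - w2 - w3, w2, w3)
  bary <- pmin(pmax(bary, 0), 1)
  bary <- bary / sum(bary)
  list(triangle = best, point = q, dist = sqrt(d2p[best]), bary = bary)
}

# precompute triangle corner matrices plus centroid bounds for pruning
mesh_query_data <- function(mesh) {
  v <- mesh$vertices; f <- mesh$triangles
  A <- v[f[, 1], , drop = FALSE]
  B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  centroid <- (A + B + C) / 3
  rad <- pmax(row_norms(A - centroid), row_norms(B - centroid),
              row_norms(C - centroid))
  ab <- B - A; ac <- C - A
  nrm <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
               ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
               ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  nrm <- nrm / row_norms(nrm)
  list(A = A, B = B, C = C, centroid = centroid, rad = rad, normal = nrm)
}

#' Closest point on a mesh for a set of query points
#'
#' For each query point, finds the closest point on the triangulated
#' surface, the containing triangle, its barycentric weights, and the
#' distance.  The signed distance is positive on the side the triangle
#' normals (winding) point to -- outward by package convention -- and
#' negative underneath the surface.
#'
#' @param points n x 3 matrix of query positions (mm).
#' @param mesh a [surface_mesh()].
#' @return tibble with columns `triangle`, `dist`, `signed_dist`,
#'   `bary1..3`, `cx`, `cy`, `cz` (closest point).
#' @export
closest_point_on_mesh <- function(points, mesh) {
  pts <- as_points3(points, "query points")
  qd <- mesh_query_data(mesh)
  n <- nrow(pts)
  out_tri <- integer(n); out_d <- double(n); out_sd <- double(n)
  out_b <- matrix(0, n, 3); out_c <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    p <- pts[i, ]
    cd <- sqrt(colSums((t(qd$centroid) - p)^2))
    ub <- min(cd + qd$rad)          # an attainable distance
    cand <- which(cd - qd$rad <= ub)
    res <- closest_on_triangles(p, qd$A[cand, , drop = FALSE],
                                qd$B[cand, , drop = FALSE],
                                qd$C[cand, , drop = FALSE])
    tri <- cand[res$triangle]
    out_tri[i] <- tri
    out_d[i] <- res$dist
    out_sd[i] <- res$dist * sign(sum((p - res$point) * qd$normal[tri, ]))
    out_b[i, ] <- res$bary
    out_c[i, ] <- res$point
  }
  tibble::tibble(triangle = out_tri, dist = out_d, signed_dist = out_sd,
                 bary1 = out_b[, 1], bary2 = out_b[, 2], bary3 = out_b[, 3],
                 cx = out_c[, 1], cy = out_c[, 2], cz = out_c[, 3])
}
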