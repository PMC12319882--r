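#' Surrounding vertices of a streamline endpoint
#'
#' Finds the closest point on the surface mesh and returns the three
#' vertices of its containing triangle -- the vertices "surrounding" the
#' endpoint -- together with barycentric weights.  Endpoints farther than
#' `tol` mm from the mesh are flagged as off-surface.
#'
#' @param p 3-vector endpoint position (mm).
#' @param mesh a [surface_mesh()].
#' @param tol off-surface tolerance in mm (default 2).
#' @return list with `vertices` (3 indices), `weights` (barycentric),
#'   `triangle`, `dist`, and `ok` (`FALSE` when beyond tolerance).
#' @export
endpoint_vertices <- function(p, mesh, tol = 2) {
  cp <- closest_point_on_mesh(matrix(p, 1, 3), mesh)
  tri <- mesh$triangles[cp$triangle[1], ]
  list(vertices = as.integer(tri),
       weights = c(cp$bary1[1], cp$bary2[1], cp$bary3[1]),
       triangle = cp$triangle[1],
       dist = cp$dist[1],
       ok = cp$dist[1] <= tol)
}

#' Projection parameters
#'
#' @param tol off-surface endpoint tolerance in mm.
#' @param weighted use barycentric-weighted endpoint means instead of the
#'   unweighted mean over the three surrounding vertices.
#' @param strict error (rather than skip) on streamlines without a unique
#'   V1-side endpoint.
#' @return a list with class `"projection_params"`.
#' @export
projection_params <- function(tol = 2, weighted = FALSE, strict = FALSE) {
  structure(list(tol = tol, weighted = weighted, strict = strict),
            class = "projection_params")
}

# mean of the three surrounding vertex values; circular for polar angle
endpoint_mean <- function(values, weights, circular, weighted) {
  if (anyNA(values)) return(NA_real_)
  if (!weighted) weights <- rep(1 / 3, 3)
  if (circular) {
    r <- deg2rad(values)
    wrap_degrees(rad2deg(atan2(sum(weights * sin(r)), sum(weights * cos(r)))))
  } else {
    sum(weights * values) / sum(weights)
  }
}

#' Project retinotopy onto V1--V2 streamlines
#'
#' For each streamline, the three mesh vertices surrounding each endpoint
#' are identified and the mean eccentricity and polar angle over them
#' computed (circular mean for polar angle), giving four retinotopy values
#' per streamline.  The value carried by the streamline along its entire
#' length is its V1-end mean.  The V1 end is the endpoint whose assigned
#' triangle lies in the V1 surface label (majority of its vertices);
#' streamlines whose two endpoints are both (or neither) in V1 are
#' flagged and skipped (or raise an error with `strict = TRUE`).
#' Endpoints landing on unvalued (unreliable) map vertices leave the
#' corresponding mean `NA` and flag the streamline.  When ribbon surfaces
#' are supplied, streamlines exceeding the intracortical-fraction
#' threshold are removed before projection.
#'
#' @param t a [tractogram()].
#' @param mesh the white [surface_mesh()] carrying the maps.
#' @param ecc,pol [vertex_scalar_map()]s (eccentricity / polar angle).
#' @param v1,v2 surface [cortical_label()]s (disjoint).
#' @param params a [projection_params()].
#' @param white,pial optional ribbon surfaces enabling the intracortical
#'   filter.
#' @param sel_params a [selection_params()] supplying the intracortical
#'   threshold.
#' @return list with `endpoints` (tibble, one row per endpoint: streamline,
#'   end, the three vertices, mean_eccentricity, mean_polar_angle),
#'   `streamlines` (tibble, one row per projected streamline with its
#'   carried V1-end values and V1-end position) and `dropped` (tibble of
#'   excluded streamlines with reasons).
#' @export
project_retinotopy <- function(t, mesh, ecc, pol, v1, v2,
                               params = projection_params(),
                               white = NULL, pial = NULL,
                               sel_params = selection_params()) {
  stopifnot(inherits(t, "tractogram"), inherits(mesh, "surface_mesh"))
  stopifnot(ecc$kind == "eccentricity", pol$kind == "polar_angle")
  if (length(ecc) != n_vertices(mesh) || length(pol) != n_vertices(mesh)) {
    abort("maps are not bound to this mesh")
  }
  if (is.null(v1$vertices) || is.null(v2$vertices)) {
    abort("projection needs surface-based V1/V2 labels")
  }
  if (length(intersect(v1$vertices, v2$vertices))) {
    abort("V1 and V2 labels overlap; resolve the overlap first")
  }

  ids <- seq_along(t$streamlines)
  dropped <- tibble::tibble(streamline = integer(), reason = character())
  if (!is.null(white) && !is.null(pial)) {
    check_ribbon(white, pial)
    icf <- vapply(t$streamlines, intracortical_fraction_unchecked, numeric(1),
                  white = white, pial = pial)
    bad <- icf > sel_params$intracortical_max_fraction
    dropped <- dplyr::bind_rows(dropped,
      tibble::tibble(streamline = ids[bad], reason = "intracortical"))
    t <- subset_tractogram(t, !bad)
    ids <- ids[!bad]
  }

  ecc_vals <- ifelse(ecc$valid, ecc$values, NA_real_)
  pol_vals <- ifelse(pol$valid, pol$values, NA_real_)
  in_v1 <- seq_len(n_vertices(mesh)) %in% v1$vertices
  in_v2 <- seq_len(n_vertices(mesh)) %in% v2$vertices

  ep_rows <- list(); sl_rows <- list()
  for (j in seq_along(t$streamlines)) {
    s <- t$streamlines[[j]]
    id <- ids[j]
    ends <- list(first = s[1, ], last = s[nrow(s), ])
    ev <- lapply(ends, endpoint_vertices, mesh = mesh, tol = params$tol)
    if (!ev$first$ok || !ev$last$ok) {
      dropped <- dplyr::bind_rows(dropped,
        tibble::tibble(streamline = id, reason = "off_surface"))
      next
    }
    v1_side <- vapply(ev, function(e) sum(in_v1[e$vertices]) >= 2, logical(1))
    v2_side <- vapply(ev, function(e) sum(in_v2[e$vertices]) >= 2, logical(1))
    if (sum(v1_side) != 1) {
      if (params$strict) abort(sprintf("streamline %d has no unique V1-side endpoint", id))
      dropped <- dplyr::bind_rows(dropped,
        tibble::tibble(streamline = id, reason = "ambiguous_v1_end"))
      next
    }
    which_v1 <- which(v1_side)
    tags <- c("V2", "V2"); tags[which_v1] <- "V1"

    means <- lapply(ev, function(e) {
      list(ecc = endpoint_mean(ecc_vals[e$vertices], e$weights, FALSE, params$weighted),
           pol = endpoint_mean(pol_vals[e$vertices], e$weights, TRUE, params$weighted))
    })
    for (k in 1:2) {
      e <- ev[[k]]
      ep_rows[[length(ep_rows) + 1L]] <- tibble::tibble(
        streamline = id, end = tags[k],
        vertex1 = e$vertices[1], vertex2 = e$vertices[2], vertex3 = e$vertices[3],
        dist_mm = e$dist,
        mean_eccentricity = means[[k]]$ecc,
        mean_polar_angle = means[[k]]$pol)
    }
    v1m <- means[[which_v1]]
    p_v1 <- ends[[which_v1]]
    sl_rows[[length(sl_rows) + 1L]] <- tibble::tibble(
      streamline = id,
      projected_eccentricity = v1m$ecc,
      projected_polar_angle = v1m$pol,
      v1_end_x = p_v1[1], v1_end_y = p_v1[2], v1_end_z = p_v1[3],
      v2_in_v2 = v2_side[-which_v1][[1]],
      unvalued = is.na(v1m$ecc) || is.na(v1m$pol))
  }
  endpoints <- if (length(ep_rows)) dplyr::bind_rows(ep_rows) else
    tibble::tibble(streamline = integer(), end = character(),
                   vertex1 = integer(), vertex2 = integer(), vertex3 = integer(),
                   dist_mm = double(), mean_eccentricity = double(),
                   mean_polar_angle = double())
  streamlines <- if (length(sl_rows)) dplyr::bind_rows(sl_rows) else
    tibble::tibble(streamline = integer(), projected_eccentricity = double(),
                   projected_polar_angle = double(), v1_end_x = double(),
                   v1_end_y = double(), v1_end_z = double(),
                   v2_in_v2 = logical(), unvalued = logical())
  list(endpoints = endpoints, streamlines = streamlines, dropped = dropped)
}

#' Topographic band labels along a direction
#'
#' Partitions an extent into `n_bands` contiguous, non-overlapping,
#' equal-width bands along a direction -- the programmatic analogue of
#' label strips drawn below the V1 cortical border in the polar-angle or
#' eccentricity direction.  Given a numeric range, bands are coordinate
#' intervals along the direction axis; given an ordered vertex path on a
#' mesh, vertices are assigned to equal-arc-length bands along the path.
#'
#' @param x either a numeric length-2 range `c(lo, hi)` of coordinates
#'   along the direction axis, or an integer vector of ordered vertex
#'   indices (a path) when `mesh` is supplied.
#' @param n_bands number of bands (>= 2).
#' @param direction tag recording which retinotopic direction the bands
#'   follow (`"eccentricity"` or `"polar_angle"`).
#' @param mesh the [surface_mesh()] carrying a vertex path.
#' @return tibble with one row per band: `band`, `lo`, `hi` (coordinates
#'   or arc lengths along the path), `direction`, and for vertex paths a
#'   list-column `vertices`.
#' @export
band_labels <- function(x, n_bands, direction = c("eccentricity", "polar_angle"),
                        mesh = NULL) {
  direction <- match.arg(direction)
  n_bands <- as.integer(n_bands)
  if (n_bands < 2) abort("need at least 2 bands")
  if (is.null(mesh)) {
    rng <- as.numeric(x)
    if (length(rng) != 2 || !all(is.finite(rng)) || rng[1] >= rng[2]) {
      abort("degenerate direction: range must be two increasing finite values")
    }
    br <- seq(rng[1], rng[2], length.out = n_bands + 1L)
    tibble::tibble(band = seq_len(n_bands), lo = br[-(n_bands + 1L)], hi = br[-1],
                   direction = direction)
  } else {
    path <- as.integer(x)
    if (length(path) < 2) abort("vertex path must have at least 2 vertices")
    pts <- mesh$vertices[path, , drop = FALSE]
    s <- c(0, cumsum(row_norms(diff(pts))))
    L <- s[length(s)]
    if (L <= 0) abort("degenerate direction: zero-length vertex path")
    br <- seq(0, L, length.out = n_bands + 1L)
    idx <- pmin(findInterval(s, br, rightmost.closed = TRUE), n_bands)
    tibble::tibble(band = seq_len(n_bands),
                   lo = br[-(n_bands + 1L)], hi = br[-1],
                   direction = direction,
                   vertices = lapply(seq_len(n_bands), function(b) path[idx == b]))
  }
}

#' Cluster streamlines into topographic bands
#'
#' Assigns each projected streamline to the band containing the coordinate
#' of its V1-end along the band direction axis, giving an ordered
#' topographic clustering with a deterministic colour per cluster.
#'
#' @param proj the `streamlines` tibble from [project_retinotopy()] (or
#'   any tibble with a `streamline` column and V1-end coordinates).
#' @param bands a band tibble from [band_labels()] (range form).
#' @param axis_origin,axis_direction origin and unit direction of the
#'   band axis in world mm; V1-end positions are projected onto it.
#' @return a `"saf_clustering"` tibble: `streamline`, `position` (mm along
#'   the axis), `cluster` (band id, `NA` when outside all bands) and
#'   `colour`.  Unassigned streamlines are reported.
#' @export
cluster_by_band <- function(proj, bands, axis_origin = c(0, 0, 0),
                            axis_direction = c(0, 1, 0)) {
  stopifnot(all(c("v1_end_x", "v1_end_y", "v1_end_z") %in% names(proj)))
  u <- axis_direction / sqrt(sum(axis_direction^2))
  pos <- as.matrix(proj[, c("v1_end_x", "v1_end_y", "v1_end_z")])
  pos <- sweep(pos, 2, axis_origin)
  coord <- as.vector(pos %*% u)
  br <- c(bands$lo, bands$hi[nrow(bands)])
  cl <- findInterval(coord, br, rightmost.closed = TRUE)
  cl[cl < 1 | cl > nrow(bands)] <- NA_integer_
  if (anyNA(cl)) {
    inform(sprintf("%d streamline(s) fall outside all bands and are unassigned", sum(is.na(cl))))
  }
  pal <- grDevices::hcl.colors(nrow(bands), palette = "Spectral")
  out <- tibble::tibble(streamline = proj$streamline, position = coord,
                        cluster = cl, colour = pal[cl])
  class(out) <- c("saf_clustering", class(out))
  attr(out, "bands") <- bands
  out
}

#' Topographic order index
#'
#' Spearman rank correlation between per-streamline projected retinotopy
#' values and per-streamline positions along a reference axis, in
#' `[-1, 1]`.  Circular values (polar angle) are unwrapped against the
#' position order before ranking.  Constant values make the index
#' undefined; it is reported as 0 with a warning.
#'
#' @param values per-streamline projected retinotopy values.
#' @param positions per-streamline coordinate along the reference axis.
#' @param circular treat `values` as angles in degrees.
#' @return Spearman correlation (scalar).
#' @export
topographic_order_index <- function(values, positions, circular = FALSE) {
  ok <- !is.na(values) & !is.na(positions)
  values <- values[ok]; positions <- positions[ok]
  if (length(values) < 3) abort("need at least 3 streamlines with values and positions")
  if (circular) {
    ord <- order(positions)
    v <- values[ord]
    d <- angdiff_deg(v[-1], v[-length(v)])
    unwrapped <- cumsum(c(v[1], d))
    # re-associate unwrapped values with their original streamlines
    values <- numeric(length(v))
    values[ord] <- unwrapped
  }
  if (sd(values) == 0 || sd(positions) == 0) {
    warn("constant values: topographic order index undefined, reported as 0")
    return(0)
  }
  cor(values, positions, method = "spearman")
}
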