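#' Selection and geometry parameters for SAF post-processing
#'
#' Bundles the per-streamline filter settings: length bounds, maximum
#' intracortical fraction, deep white-matter exclusion depth, and the
#' arc-length resampling step used for curvature estimation.  The
#' `"invivo"` preset keeps streamlines of 3--120 mm with a 0.2 mm step;
#' the `"postmortem"` preset restricts lengths to 3--30 mm with a 0.1 mm
#' step, matching the higher-resolution specimen protocol.
#'
#' @param preset `"invivo"` or `"postmortem"`; sets defaults which the
#'   explicit arguments below override.
#' @param min_length,max_length streamline length bounds in mm.
#' @param intracortical_max_fraction maximum tolerated fraction of arc
#'   length inside the cortical ribbon (default 0.8).
#' @param deep_exclusion_depth depth below the white surface (mm) beyond
#'   which streamlines are excluded (default 2).
#' @param resample_step arc-length resampling step in mm.
#' @return a list with class `"selection_params"`.
#' @export
selection_params <- function(preset = c("invivo", "postmortem"),
                             min_length = 3,
                             max_length = NULL,
                             intracortical_max_fraction = 0.8,
                             deep_exclusion_depth = 2,
                             resample_step = NULL) {
  preset <- match.arg(preset)
  if (is.null(max_length)) max_length <- if (preset == "invivo") 120 else 30
  if (is.null(resample_step)) resample_step <- if (preset == "invivo") 0.2 else 0.1
  if (!(0 < min_length && min_length < max_length)) abort("need 0 < min_length < max_length")
  if (!(0 < intracortical_max_fraction && intracortical_max_fraction <= 1)) {
    abort("intracortical_max_fraction must be in (0, 1]")
  }
  if (deep_exclusion_depth <= 0) abort("deep_exclusion_depth must be positive")
  if (resample_step <= 0) abort("resample_step must be positive")
  structure(list(preset = preset, min_length = min_length, max_length = max_length,
                 intracortical_max_fraction = intracortical_max_fraction,
                 deep_exclusion_depth = deep_exclusion_depth,
                 resample_step = resample_step),
            class = "selection_params")
}

#' Arc length of a streamline
#'
#' Sum of consecutive point-to-point distances, in mm.
#'
#' @param s a [streamline()] or n x 3 matrix.
#' @return arc length in mm (strictly positive).
#' @export
arc_length <- function(s) {
  m <- as_points3(s, "streamline")
  if (nrow(m) < 2) abort("arc length needs at least 2 points")
  sum(row_norms(diff(m)))
}

#' Resample a streamline at a uniform arc-length step
#'
#' Points are placed every `step` mm along the polyline; the original
#' endpoints are preserved exactly, so the last segment may be shorter
#' than `step`.  A step at or beyond the total length returns the two
#' endpoints.
#'
#' @param s a [streamline()].
#' @param step arc-length spacing in mm.
#' @return a resampled [streamline()].
#' @export
resample_streamline <- function(s, step) {
  m <- as_points3(s, "streamline")
  if (step <= 0) abort("step must be positive")
  cs <- c(0, cumsum(row_norms(diff(m))))
  L <- cs[length(cs)]
  if (step >= L) return(streamline(m[c(1, nrow(m)), , drop = FALSE]))
  # uniform spacing <= step that divides the length exactly, so the
  # arc-length parameterisation stays strictly regular
  targets <- seq(0, L, length.out = max(2L, ceiling(L / step - 1e-9) + 1L))
  out <- vapply(1:3, function(k) stats::approx(cs, m[, k], xout = targets, ties = "ordered")$y,
                numeric(length(targets)))
  out[1, ] <- m[1, ]; out[nrow(out), ] <- m[nrow(m), ]
  # collapse numerically coincident samples (can arise at the appended endpoint)
  keep <- c(TRUE, row_norms(diff(out)) > 1e-12)
  streamline(out[keep, , drop = FALSE])
}

#' Apex and bending angle of a streamline
#'
#' The streamline is resampled at a uniform arc-length step; discrete
#' curvature magnitude is estimated at interior points by central second
#' differences on the arc-length parameterisation (after an optional
#' 3-point coordinate smoothing that stabilises noisy polylines).  The
#' apex is the interior point of maximum curvature (the two points
#' adjacent to the endpoints are not candidates, as endpoint smoothing
#' makes their curvature estimates unstable), with ties broken towards
#' the arc-length midpoint; a streamline whose maximum curvature is
#' negligible is treated as straight, with the apex at the midpoint.  The
#' bending angle is the angle in degrees between the vectors joining the
#' apex to the two endpoints: 180 for a straight line, smaller for more
#' U-shaped fibres.
#'
#' @param s a [streamline()].
#' @param params a [selection_params()] (supplies `resample_step`).
#' @param presmooth apply the 3-point coordinate smoothing before
#'   differencing (default `TRUE`).  The apex position is always taken
#'   from the unsmoothed resampled polyline.
#' @return list with `apex_index`, `apex_position` (3-vector, mm),
#'   `bending_angle` (degrees in `[0, 180]`) and `degenerate` (fewer than
#'   3 resampled points: angle `NA`).
#' @export
apex_and_bending_angle <- function(s, params = selection_params(), presmooth = TRUE) {
  r <- resample_streamline(s, params$resample_step)
  n <- nrow(r)
  if (n < 3) {
    return(list(apex_index = NA_integer_, apex_position = c(NA_real_, NA_real_, NA_real_),
                bending_angle = NA_real_, degenerate = TRUE))
  }
  w <- unclass(r)
  if (presmooth && n >= 3) {
    sm <- w
    sm[2:(n - 1), ] <- (w[1:(n - 2), ] + w[2:(n - 1), ] + w[3:n, ]) / 3
  } else {
    sm <- w
  }
  # non-uniform central second difference on the arc-length
  # parameterisation (the final resampled segment may be shorter)
  cs <- c(0, cumsum(row_norms(diff(w))))
  h1 <- cs[2:(n - 1)] - cs[1:(n - 2)]
  h2 <- cs[3:n] - cs[2:(n - 1)]
  sec <- 2 * (h1 * sm[3:n, , drop = FALSE] -
                (h1 + h2) * sm[2:(n - 1), , drop = FALSE] +
                h2 * sm[1:(n - 2), , drop = FALSE]) / (h1 * h2 * (h1 + h2))
  curv <- row_norms(sec)                       # at interior points 2..n-1

  mid_s <- cs[n] / 2
  interior <- seq_along(curv)                  # curvature index i -> point i+1
  if (n >= 6) interior <- interior[-c(1L, length(interior))]
  cmax <- max(curv[interior])
  if (cmax < 1e-4) {                           # straight: degenerate curvature field
    apex <- which.min(abs(cs - mid_s))
  } else {
    cand <- interior[curv[interior] >= cmax * (1 - 1e-6)] + 1L
    apex <- cand[which.min(abs(cs[cand] - mid_s))]
  }
  ang <- vec_angle_deg(w[apex, ] - w[1, ], w[apex, ] - w[n, ])
  if (is.na(ang)) ang <- 180                   # apex coincides with an endpoint
  list(apex_index = apex, apex_position = w[apex, ],
       bending_angle = ang, degenerate = FALSE)
}

#' Does a streamline traverse both labels?
#'
#' `TRUE` when at least one point lies inside `v1` and at least one inside
#' `v2` (voxel membership after world-to-voxel rounding, or surface-label
#' membership via the nearest labelled vertex within `tol`).
#'
#' @param s a [streamline()].
#' @param v1,v2 [cortical_label()]s on a common world frame.
#' @param mesh carrying mesh for surface labels.
#' @param tol nearest-vertex tolerance (mm) for surface labels.
#' @return logical scalar.
#' @export
connects_labels <- function(s, v1, v2, mesh = NULL, tol = 2) {
  m <- as_points3(s, "streamline")
  any(label_contains(v1, m, mesh = mesh, tol = tol)) &&
    any(label_contains(v2, m, mesh = mesh, tol = tol))
}

#' Select streamlines connecting V1 and V2
#'
#' @param t a [tractogram()].
#' @inheritParams connects_labels
#' @return filtered [tractogram()] with a `counts` attribute
#'   `c(n_in, n_kept, n_removed)`.
#' @export
select_connecting <- function(t, v1, v2, mesh = NULL, tol = 2) {
  keep <- vapply(t$streamlines, connects_labels, logical(1),
                 v1 = v1, v2 = v2, mesh = mesh, tol = tol)
  out <- subset_tractogram(t, keep)
  attr(out, "counts") <- c(n_in = length(t), n_kept = sum(keep),
                           n_removed = sum(!keep))
  out
}

#' Length filter
#'
#' Keeps streamlines whose arc length lies within the closed interval
#' `[min_length, max_length]`.
#'
#' @param t a [tractogram()].
#' @param params a [selection_params()].
#' @return filtered [tractogram()] with a `counts` attribute.
#' @export
length_filter <- function(t, params = selection_params()) {
  len <- vapply(t$streamlines, arc_length, numeric(1))
  keep <- len >= params$min_length & len <= params$max_length
  out <- subset_tractogram(t, keep)
  attr(out, "counts") <- c(n_in = length(t), n_kept = sum(keep),
                           n_removed = sum(!keep))
  out
}

# ribbon sanity check: white vertices must lie under the pial surface
check_ribbon <- function(white, pial, n_sample = 50) {
  idx <- unique(round(seq(1, n_vertices(white), length.out = min(n_sample, n_vertices(white)))))
  sd_pial <- closest_point_on_mesh(white$vertices[idx, , drop = FALSE], pial)$signed_dist
  if (mean(sd_pial > 1e-6) > 0.5) {
    abort("pial surface lies inside the white surface: not a cortical ribbon")
  }
  invisible(TRUE)
}

#' Intracortical fraction of a streamline
#'
#' Fraction of arc length lying inside the cortical ribbon, i.e. at points
#' above the white surface and below the pial surface (signed-distance
#' tests against each mesh, whose winding defines outward).  The
#' streamline is resampled at a uniform `step` so the point fraction
#' estimates the arc-length fraction.
#'
#' @param s a [streamline()].
#' @param white,pial [surface_mesh()]es bounding the ribbon.
#' @param step resampling step in mm (default 0.5).
#' @return fraction in `[0, 1]`.
#' @export
intracortical_fraction <- function(s, white, pial, step = 0.5) {
  check_ribbon(white, pial)
  intracortical_fraction_unchecked(s, white, pial, step)
}

intracortical_fraction_unchecked <- function(s, white, pial, step = 0.5) {
  r <- resample_streamline(s, step)
  sd_w <- closest_point_on_mesh(r, white)$signed_dist
  sd_p <- closest_point_on_mesh(r, pial)$signed_dist
  mean(sd_w >= 0 & sd_p <= 0)
}

#' Intracortical-fraction filter over a tractogram
#'
#' Removes streamlines with more than `params$intracortical_max_fraction`
#' of their length inside the cortical ribbon (default: more than 80%),
#' which would otherwise bias the projection of retinotopy onto fibres.
#'
#' @param t a [tractogram()].
#' @param white,pial ribbon surfaces.
#' @param params a [selection_params()].
#' @param step resampling step for the point-in-ribbon test (mm).
#' @return filtered [tractogram()] with `counts` and `icf` attributes.
#' @export
intracortical_filter <- function(t, white, pial, params = selection_params(),
                                 step = 0.5) {
  check_ribbon(white, pial)
  icf <- vapply(t$streamlines, intracortical_fraction_unchecked, numeric(1),
                white = white, pial = pial, step = step)
  keep <- icf <= params$intracortical_max_fraction
  out <- subset_tractogram(t, keep)
  attr(out, "counts") <- c(n_in = length(t), n_kept = sum(keep),
                           n_removed = sum(!keep))
  attr(out, "icf") <- icf
  out
}

#' Deep white-matter exclusion
#'
#' Removes streamlines that have any point deeper than `depth` mm below
#' the white surface (negative signed distance beyond the threshold),
#' separating superficial U-fibres from long-range pathways that dive
#' into the deep white matter.
#'
#' @param t a [tractogram()].
#' @param white the white [surface_mesh()].
#' @param depth exclusion depth in mm (default from `params`); `Inf`
#'   disables the filter.
#' @param params a [selection_params()].
#' @param step resampling step for the depth test (mm).
#' @return filtered [tractogram()] with a `counts` attribute.
#' @export
deep_wm_exclusion <- function(t, white, depth = NULL,
                              params = selection_params(), step = 0.5) {
  depth <- depth %||% params$deep_exclusion_depth
  if (is.infinite(depth)) {
    out <- subset_tractogram(t, rep(TRUE, length(t)))
    attr(out, "counts") <- c(n_in = length(t), n_kept = length(t), n_removed = 0L)
    return(out)
  }
  keep <- vapply(t$streamlines, function(s) {
    r <- resample_streamline(s, step)
    sd_w <- closest_point_on_mesh(r, white)$signed_dist
    !any(sd_w < -depth)
  }, logical(1))
  out <- subset_tractogram(t, keep)
  attr(out, "counts") <- c(n_in = length(t), n_kept = sum(keep),
                           n_removed = sum(!keep))
  out
}

#' Per-streamline geometry table
#'
#' Computes arc length, apex and bending angle for every streamline, and
#' (when ribbon surfaces are supplied) the intracortical fraction.
#'
#' @param t a [tractogram()].
#' @param params a [selection_params()].
#' @param white,pial optional ribbon surfaces for the intracortical
#'   fraction column.
#' @param surface_step resampling step for surface tests (mm).
#' @return tibble with one row per streamline: `streamline`, `length_mm`,
#'   `bending_angle_deg`, `apex_index`, `apex_x/y/z`, `degenerate`, and
#'   `intracortical_fraction` when surfaces are given.
#' @export
streamline_geometry <- function(t, params = selection_params(),
                                white = NULL, pial = NULL, surface_step = 0.5) {
  stopifnot(inherits(t, "tractogram"))
  rows <- purrr::map_dfr(seq_along(t$streamlines), function(i) {
    s <- t$streamlines[[i]]
    ab <- apex_and_bending_angle(s, params)
    tibble::tibble(streamline = i,
                   length_mm = arc_length(s),
                   bending_angle_deg = ab$bending_angle,
                   apex_index = ab$apex_index,
                   apex_x = ab$apex_position[1],
                   apex_y = ab$apex_position[2],
                   apex_z = ab$apex_position[3],
                   degenerate = ab$degenerate)
  })
  if (!is.null(white) && !is.null(pial)) {
    check_ribbon(white, pial)
    rows$intracortical_fraction <- vapply(
      t$streamlines, intracortical_fraction_unchecked, numeric(1),
      white = white, pial = pial, step = surface_step)
  }
  rows
}
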