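#' Orthonormal sheet frame of a streamline population
#'
#' With no anatomical frame supplied, the frame is the set of principal
#' axes of the pooled, centroid-centred streamline points, ordered by
#' descending variance.  Axis signs are fixed deterministically: each axis
#' is flipped to have a positive dot product with the first reference
#' direction it is not orthogonal to (anterior `+y` first, then `+x`,
#' `+z`).  A supplied anatomical frame is orthonormalised and used as-is.
#' A rank-deficient point cloud (e.g. a single straight streamline) is
#' completed with an arbitrary orthogonal complement and flagged.
#'
#' @param t a [tractogram()] with at least 2 streamlines (or 1, flagged).
#' @param anatomical_frame optional 3 x 3 matrix of axis columns.
#' @return 3 x 3 matrix of unit axis columns, with attributes `centroid`
#'   and `rank_deficient`.
#' @export
sheet_frame <- function(t, anatomical_frame = NULL) {
  pts <- pooled_points(t)
  centroid <- colMeans(pts)
  if (!is.null(anatomical_frame)) {
    q <- orthonormalise(anatomical_frame)
    attr(q, "centroid") <- centroid
    attr(q, "rank_deficient") <- FALSE
    return(q)
  }
  cc <- sweep(pts, 2, centroid)
  ev <- eigen(crossprod(cc) / (nrow(cc) - 1), symmetric = TRUE)
  q <- ev$vectors                               # descending eigenvalues
  refs <- rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1))
  for (j in 1:3) {
    for (k in 1:3) {
      d <- sum(q[, j] * refs[k, ])
      if (abs(d) > 1e-8) { if (d < 0) q[, j] <- -q[, j]; break }
    }
  }
  deficient <- ev$values[3] < 1e-10 * max(ev$values[1], 1e-300)
  if (deficient) {
    warn("rank-deficient point cloud; frame completed with an arbitrary orthogonal complement")
  }
  attr(q, "centroid") <- centroid
  attr(q, "rank_deficient") <- deficient
  q
}

#' Per-axis sheet sizes (variances)
#'
#' The size of the fibre population along each frame axis is the variance
#' (mm^2) of the pooled streamline point coordinates projected on that
#' axis.  Sizes are returned in descending order, together with the
#' correspondingly reordered frame.
#'
#' @param t a [tractogram()].
#' @param frame 3 x 3 axis matrix (columns), e.g. from [sheet_frame()].
#' @return named numeric vector `c(size1, size2, size3)` in mm^2, sorted
#'   descending, with the reordered frame in attribute `frame`.
#' @export
sheet_sizes <- function(t, frame) {
  pts <- pooled_points(t)
  q <- orthonormalise(frame)
  proj <- pts %*% q
  sizes <- apply(proj, 2, function(x) mean((x - mean(x))^2))
  ord <- order(sizes, decreasing = TRUE)
  out <- sizes[ord]
  names(out) <- paste0("size", 1:3)
  attr(out, "frame") <- q[, ord, drop = FALSE]
  out
}

#' Fit a 2D surface to the sheet
#'
#' Least-squares fit of the coordinate along the smallest axis (the sheet
#' normal) as a polynomial height function of the coordinates along the
#' two largest axes, on the centred, frame-projected pooled points.
#' The thickness size is the variance along the smallest axis, independent
#' of the fit.
#'
#' @param t a [tractogram()] with at least 6 non-degenerate points.
#' @param frame 3 x 3 axis matrix ordered by descending variance.
#' @param degree polynomial degree of the height function (1--3,
#'   default 2).
#' @return list with `coefficients` (named), `residual_sd` (mm),
#'   `thickness_size` (mm^2) and the fitted `model`.
#' @export
fit_sheet_surface <- function(t, frame, degree = 2) {
  if (!degree %in% 1:3) abort("surface degree must be 1, 2 or 3")
  pts <- pooled_points(t)
  if (nrow(pts) < 6) abort("need at least 6 points to fit a sheet surface")
  q <- orthonormalise(frame)
  cc <- sweep(pts, 2, colMeans(pts))
  uvw <- cc %*% q
  df <- tibble::tibble(u = uvw[, 1], v = uvw[, 2], w = uvw[, 3])
  terms <- c("u", "v")
  if (degree >= 2) terms <- c(terms, "I(u^2)", "I(u*v)", "I(v^2)")
  if (degree >= 3) terms <- c(terms, "I(u^3)", "I(u^2*v)", "I(u*v^2)", "I(v^3)")
  fml <- stats::as.formula(paste("w ~", paste(terms, collapse = " + ")))
  fit <- lm(fml, data = df)
  if (any(is.na(coef(fit)))) abort("underdetermined sheet-surface fit")
  res <- stats::residuals(fit)
  list(coefficients = coef(fit),
       residual_sd = sqrt(mean(res^2)),
       thickness_size = mean((uvw[, 3] - mean(uvw[, 3]))^2),
       model = fit)
}

#' Sheet-versus-bundle classification from per-axis sizes
#'
#' With sizes sorted descending (`s1 >= s2 >= s3`), the population is a
#' sheet when it is thin in exactly one direction: `s2/s3 >= ratio` while
#' `s1/s2 < comparable`.  It is a bundle when it is extended in exactly
#' one direction with a comparable small cross-section: `s1/s2 >= ratio`
#' while `s2/s3 < comparable`.  Anything else is indeterminate.  A zero
#' smallest size counts as an infinite ratio.
#'
#' @param sizes numeric vector of 3 variances (mm^2), sorted descending.
#' @param ratio dominance threshold r (default 3).
#' @param comparable comparability threshold c (default 3).
#' @return `"sheet"`, `"bundle"` or `"indeterminate"`.
#' @export
classify_geometry <- function(sizes, ratio = 3, comparable = 3) {
  s <- as.numeric(sizes)
  if (length(s) != 3 || is.unsorted(rev(s))) abort("sizes must be 3 values sorted descending")
  r12 <- if (s[2] == 0) Inf else s[1] / s[2]
  r23 <- if (s[3] == 0) Inf else s[2] / s[3]
  if (s[1] == 0) return("indeterminate")       # all mass at a point
  if (r23 >= ratio && r12 < comparable) return("sheet")
  if (r12 >= ratio && r23 < comparable) return("bundle")
  "indeterminate"
}

#' Full sheet model of a streamline population
#'
#' Convenience wrapper running [sheet_frame()], [sheet_sizes()],
#' [fit_sheet_surface()] and [classify_geometry()] and returning a single
#' fitted object with [tidy()], [glance()] and [autoplot()] methods.
#'
#' @param t a [tractogram()].
#' @param anatomical_frame optional axis matrix (see [sheet_frame()]).
#' @param degree surface polynomial degree.
#' @param ratio,comparable classification thresholds.
#' @return an object of class `"sheet_model"`.
#' @examples
#' scene <- simulate_scene(scene_config(n_fibres = 40, seed = 1))
#' sm <- sheet_model(scene$tract)
#' glance(sm)
#' @export
sheet_model <- function(t, anatomical_frame = NULL, degree = 2,
                        ratio = 3, comparable = 3) {
  frame <- sheet_frame(t, anatomical_frame)
  sizes <- sheet_sizes(t, frame)
  frame_sorted <- attr(sizes, "frame")
  surf <- fit_sheet_surface(t, frame_sorted, degree = degree)
  structure(list(
    frame = frame_sorted,
    sizes = as.numeric(sizes),
    surface_coefficients = surf$coefficients,
    residual_sd = surf$residual_sd,
    thickness_size = surf$thickness_size,
    classification = classify_geometry(as.numeric(sizes), ratio, comparable),
    ratio = ratio, comparable = comparable, degree = degree,
    centroid = attr(frame, "centroid"),
    rank_deficient = isTRUE(attr(frame, "rank_deficient")),
    n_streamlines = length(t),
    points = pooled_points(t)
  ), class = "sheet_model")
}

#' @export
print.sheet_model <- function(x, ...) {
  cat(sprintf("<sheet_model> %d streamlines, classified as %s\n",
              x$n_streamlines, x$classification))
  cat(sprintf("  sizes (mm^2): %.3g, %.3g, %.3g; residual sd %.3g mm\n",
              x$sizes[1], x$sizes[2], x$sizes[3], x$residual_sd))
  invisible(x)
}

#' @rdname sheet_model
#' @param x a `"sheet_model"`.
#' @param ... unused.
#' @method tidy sheet_model
#' @export
tidy.sheet_model <- function(x, ...) {
  tibble::tibble(
    axis = 1:3,
    size_mm2 = x$sizes,
    dx = x$frame[1, ], dy = x$frame[2, ], dz = x$frame[3, ]
  )
}

#' @rdname sheet_model
#' @method glance sheet_model
#' @export
glance.sheet_model <- function(x, ...) {
  tibble::tibble(
    n_streamlines = x$n_streamlines,
    size1_mm2 = x$sizes[1], size2_mm2 = x$sizes[2], size3_mm2 = x$sizes[3],
    thickness_size_mm2 = x$thickness_size,
    residual_sd_mm = x$residual_sd,
    classification = x$classification,
    rank_deficient = x$rank_deficient
  )
}

#' @rdname sheet_model
#' @param object a `"sheet_model"`.
#' @method autoplot sheet_model
#' @export
autoplot.sheet_model <- function(object, ...) {
  cc <- sweep(object$points, 2, colMeans(object$points))
  uvw <- cc %*% object$frame
  df <- tibble::tibble(u = uvw[, 1], v = uvw[, 2], w = uvw[, 3])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v, colour = .data$w)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::scale_colour_viridis_c(name = "height (mm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "axis 1 (mm)", y = "axis 2 (mm)",
      title = sprintf("Sheet model (%s): sizes %.1f / %.1f / %.1f mm²",
                      object$classification,
                      object$sizes[1], object$sizes[2], object$sizes[3])
    ) +
    ggplot2::theme_minimal()
}
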