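#' Plot per-streamline geometry distributions
#'
#' Histograms of streamline lengths and bending angles from a
#' [streamline_geometry()] table.
#'
#' @param geometry tibble from [streamline_geometry()].
#' @return a ggplot object.
#' @export
plot_geometry <- function(geometry) {
  df <- tidyr::pivot_longer(
    dplyr::select(geometry, "streamline", "length_mm", "bending_angle_deg"),
    cols = c("length_mm", "bending_angle_deg"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "streamlines") +
    ggplot2::theme_minimal()
}

#' @rdname cluster_by_band
#' @param object a `"saf_clustering"`.
#' @param ... unused.
#' @method autoplot saf_clustering
#' @export
autoplot.saf_clustering <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$cluster))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = factor(.data$cluster),
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_jitter(height = 0.15, width = 0, size = 0.8, show.legend = FALSE) +
    ggplot2::labs(x = "position along band axis (mm)", y = "topographic cluster") +
    ggplot2::theme_minimal()
}

#' Plot projected retinotopy against position along an axis
#'
#' Visual check of topographic order: each point is one streamline's
#' V1-end projected value against its position along the reference axis.
#'
#' @param proj `streamlines` tibble from [project_retinotopy()].
#' @param what `"eccentricity"` or `"polar_angle"`.
#' @param axis_direction unit direction of the reference axis.
#' @param axis_origin origin of the reference axis.
#' @return a ggplot object.
#' @export
plot_topography <- function(proj, what = c("eccentricity", "polar_angle"),
                            axis_direction = c(0, 1, 0),
                            axis_origin = c(0, 0, 0)) {
  what <- match.arg(what)
  u <- axis_direction / sqrt(sum(axis_direction^2))
  pos <- as.matrix(proj[, c("v1_end_x", "v1_end_y", "v1_end_z")])
  coord <- as.vector(sweep(pos, 2, axis_origin) %*% u)
  val <- if (what == "eccentricity") proj$projected_eccentricity else
    proj$projected_polar_angle
  df <- tibble::tibble(position = coord, value = val)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6, colour = "firebrick") +
    ggplot2::labs(x = "position along axis (mm)",
                  y = sprintf("projected %s (deg)", gsub("_", " ", what))) +
    ggplot2::theme_minimal()
}
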