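#' Analysis parameters for the full SAF pipeline
#'
#' Union of the reliability, selection, sheet and projection settings,
#' with the two acquisition presets: `"invivo"` keeps streamlines of
#' 3--120 mm, `"postmortem"` restricts them to 3--30 mm.
#'
#' @param preset `"invivo"` or `"postmortem"`.
#' @param reliability a [reliability_params()].
#' @param selection a [selection_params()]; defaults to the preset's.
#' @param projection a [projection_params()].
#' @param sheet_ratio,sheet_comparable [classify_geometry()] thresholds.
#' @param surface_degree sheet-surface polynomial degree.
#' @param n_bands_ecc,n_bands_polar topographic band counts (6, 15).
#' @param surface_step resampling step for surface tests, mm.
#' @return a list with class `"saf_params"`.
#' @export
saf_params <- function(preset = c("invivo", "postmortem"),
                       reliability = reliability_params(),
                       selection = NULL,
                       projection = projection_params(),
                       sheet_ratio = 3, sheet_comparable = 3,
                       surface_degree = 2,
                       n_bands_ecc = 6, n_bands_polar = 15,
                       surface_step = 0.5) {
  preset <- match.arg(preset)
  selection <- selection %||% selection_params(preset)
  structure(list(preset = preset, reliability = reliability,
                 selection = selection, projection = projection,
                 sheet_ratio = sheet_ratio, sheet_comparable = sheet_comparable,
                 surface_degree = surface_degree,
                 n_bands_ecc = n_bands_ecc, n_bands_polar = n_bands_polar,
                 surface_step = surface_step),
            class = "saf_params")
}

#' Run the full SAF analysis pipeline
#'
#' Stages, in order: (optional) SNR computation, reliability masking and
#' map smoothing from raw fMRI; V1/V2 voxel-label overlap resolution when
#' voxel labels and a probability map are given; selection of streamlines
#' traversing both V1 and V2; length filter; deep white-matter exclusion;
#' intracortical-fraction filter; per-streamline geometry; sheet model;
#' retinotopy projection; topographic band clustering in the eccentricity
#' and polar-angle directions; group summaries.  Every filtering stage
#' records input/kept/removed streamline counts, which are conserved
#' (`input = kept + removed`).
#'
#' @param tract a [tractogram()].
#' @param white,pial cortical ribbon [surface_mesh()]es.
#' @param ecc,pol [vertex_scalar_map()]s on `white` (already smoothed, or
#'   raw if `fmri` is given, in which case they are masked and smoothed
#'   here).
#' @param v1,v2 [cortical_label()]s; surface labels drive selection and
#'   projection.
#' @param params a [saf_params()].
#' @param fmri optional [fmri_timeseries()] enabling the SNR stage.
#' @param prob_v1 optional per-voxel V1 probability map enabling voxel
#'   overlap resolution.
#' @param ecc_axis origin/direction list for eccentricity banding;
#'   defaults to the anterior--posterior axis over the V1-end positions.
#' @return a `"saf_report"` list: `counts` (stage bookkeeping tibble),
#'   `geometry`, `sheet`, `projection`, `clustering_ecc`,
#'   `clustering_polar`, `order_index_ecc`, `order_index_polar`,
#'   `summary` (one-row tibble), `params`.
#' @examples
#' scene <- simulate_scene(scene_config(n_fibres = 30, seed = 2))
#' rep <- run_saf_pipeline(scene$tract, scene$white, scene$pial,
#'                         scene$eccentricity, scene$polar_angle,
#'                         scene$v1, scene$v2)
#' rep$summary
#' @export
run_saf_pipeline <- function(tract, white, pial, ecc, pol, v1, v2,
                             params = saf_params(), fmri = NULL,
                             prob_v1 = NULL, ecc_axis = NULL) {
  counts <- tibble::tibble(stage = character(), n_in = integer(),
                           n_kept = integer(), n_removed = integer())
  note <- function(stage, t_out) {
    cc <- attr(t_out, "counts")
    counts <<- dplyr::bind_rows(counts, tibble::tibble(
      stage = stage, n_in = as.integer(cc[["n_in"]]),
      n_kept = as.integer(cc[["n_kept"]]), n_removed = as.integer(cc[["n_removed"]])))
    t_out
  }

  # --- map conditioning -------------------------------------------------
  if (!is.null(fmri)) {
    snr <- compute_snr(fmri)
    mask <- reliable_mask(snr, params$reliability)
    ecc <- smooth_vertex_map(ecc, white, mask, params$reliability)
    pol <- smooth_vertex_map(pol, white, mask, params$reliability)
  }

  # --- label resolution -------------------------------------------------
  if (!is.null(prob_v1) && !is.null(v1$voxels) && !is.null(v2$voxels)) {
    res <- resolve_label_overlap(v1, v2, prob_v1)
    v1 <- res$v1; v2 <- res$v2
  }

  # --- streamline selection and filters ---------------------------------
  t1 <- note("v1_v2_selection",
             select_connecting(tract, v1, v2, mesh = white,
                               tol = params$projection$tol))
  t2 <- note("length_filter", length_filter(t1, params$selection))
  t3 <- note("deep_wm_exclusion",
             deep_wm_exclusion(t2, white, params = params$selection,
                               step = params$surface_step))
  t4 <- note("intracortical_filter",
             intracortical_filter(t3, white, pial, params$selection,
                                  step = params$surface_step))
  if (length(t4) == 0) {
    warn("no streamlines survive the filters; returning an empty report")
  }

  # --- geometry and sheet model ----------------------------------------
  geometry <- streamline_geometry(t4, params$selection)
  sheet <- if (length(t4) >= 2) {
    sheet_model(t4, degree = params$surface_degree,
                ratio = params$sheet_ratio, comparable = params$sheet_comparable)
  } else NULL

  # --- projection and clustering ---------------------------------------
  proj <- if (length(t4) > 0) {
    project_retinotopy(t4, white, ecc, pol, v1, v2, params$projection)
  } else NULL
  clustering_ecc <- clustering_polar <- NULL
  order_ecc <- order_pol <- NA_real_
  if (!is.null(proj) && nrow(proj$streamlines) >= 3) {
    st <- proj$streamlines
    if (is.null(ecc_axis)) {
      ecc_axis <- list(origin = c(0, 0, 0), direction = c(0, 1, 0))
    }
    u <- ecc_axis$direction / sqrt(sum(ecc_axis$direction^2))
    pos <- as.matrix(st[, c("v1_end_x", "v1_end_y", "v1_end_z")])
    coord <- as.vector(sweep(pos, 2, ecc_axis$origin) %*% u)
    rng <- range(coord)
    if (diff(rng) > 0) {
      bands_e <- band_labels(rng, params$n_bands_ecc, "eccentricity")
      clustering_ecc <- cluster_by_band(st, bands_e, ecc_axis$origin,
                                        ecc_axis$direction)
    }
    # polar direction: across the fold, orthogonal to the A-P axis;
    # use the V1-end spread orthogonal to the eccentricity axis
    resid <- sweep(pos, 2, colMeans(pos))
    resid <- resid - outer(as.vector(resid %*% u), u)
    if (max(row_norms(resid)) > 1e-9) {
      w <- svd(resid, nu = 0, nv = 1)$v[, 1]
      cpos <- as.vector(sweep(pos, 2, colMeans(pos)) %*% w)
      rngp <- range(cpos)
      if (diff(rngp) > 0) {
        bands_p <- band_labels(rngp, params$n_bands_polar, "polar_angle")
        clustering_polar <- cluster_by_band(st, bands_p, colMeans(pos), w)
      }
      if (sd(st$projected_polar_angle, na.rm = TRUE) > 0) {
        order_pol <- abs(topographic_order_index(st$projected_polar_angle,
                                                 cpos, circular = TRUE))
      }
    }
    if (sd(st$projected_eccentricity, na.rm = TRUE) > 0) {
      order_ecc <- abs(topographic_order_index(st$projected_eccentricity, coord))
    }
  }

  summary <- tibble::tibble(
    n_selected = length(t4),
    mean_length_mm = if (nrow(geometry)) mean(geometry$length_mm) else NA_real_,
    sd_length_mm = if (nrow(geometry) > 1) sd(geometry$length_mm) else NA_real_,
    mean_bending_angle_deg = if (nrow(geometry))
      mean(geometry$bending_angle_deg, na.rm = TRUE) else NA_real_,
    sd_bending_angle_deg = if (nrow(geometry) > 1)
      sd(geometry$bending_angle_deg, na.rm = TRUE) else NA_real_,
    size1_mm2 = if (!is.null(sheet)) sheet$sizes[1] else NA_real_,
    size2_mm2 = if (!is.null(sheet)) sheet$sizes[2] else NA_real_,
    size3_mm2 = if (!is.null(sheet)) sheet$sizes[3] else NA_real_,
    classification = if (!is.null(sheet)) sheet$classification else NA_character_,
    order_index_ecc = order_ecc,
    order_index_polar = order_pol)

  structure(list(counts = counts, geometry = geometry, sheet = sheet,
                 projection = proj, clustering_ecc = clustering_ecc,
                 clustering_polar = clustering_polar,
                 order_index_ecc = order_ecc, order_index_polar = order_pol,
                 summary = summary, params = params,
                 tract_selected = t4),
            class = "saf_report")
}

#' @export
print.saf_report <- function(x, ...) {
  cat("<saf_report>\n")
  cat("stage bookkeeping:\n")
  print(as.data.frame(x$counts), row.names = FALSE)
  s <- x$summary
  cat(sprintf("\n%d selected streamlines: length %.1f +/- %.1f mm, bending angle %.1f +/- %.1f deg\n",
              s$n_selected, s$mean_length_mm, s$sd_length_mm,
              s$mean_bending_angle_deg, s$sd_bending_angle_deg))
  if (!is.na(s$classification)) {
    cat(sprintf("sheet sizes %.2g / %.2g / %.2g mm^2 (%s); order index ecc %.3f, polar %.3f\n",
                s$size1_mm2, s$size2_mm2, s$size3_mm2, s$classification,
                s$order_index_ecc, s$order_index_polar))
  }
  invisible(x)
}

#' @rdname run_saf_pipeline
#' @param x a `"saf_report"`.
#' @param ... unused.
#' @method glance saf_report
#' @export
glance.saf_report <- function(x, ...) x$summary

#' @rdname run_saf_pipeline
#' @method tidy saf_report
#' @export
tidy.saf_report <- function(x, ...) x$geometry
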