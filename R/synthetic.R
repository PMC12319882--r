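#' Configuration of a synthetic folded-gyrus scene
#'
#' The phantom emulates a single gyral fold at the V1--V2 interface: a
#' V-shaped cross-section (two cortical banks meeting at a rounded sulcal
#' apex) extruded along the anterior--posterior (+y) axis.  Short
#' association fibres run beneath the white surface from one bank across
#' the apex to the other, all at a fixed depth, forming a sheet.
#' Retinotopy is smooth: eccentricity increases linearly along the
#' anterior--posterior extent (default 3 to 6.9 degrees, the range a
#' phase-encoded experiment can stimulate), polar angle linearly along the
#' cross-fold arc.  Phase-encoded fMRI responses are sinusoids at the
#' stimulus frequency whose phase encodes the retinotopic coordinate, plus
#' Gaussian noise.
#'
#' The fold "sharpness" is parameterised directly by the target apex
#' angle of the fibres: large angles (e.g. 140 degrees) give the shallow
#' V-shapes typical of the V1--V2 gyrus, small angles give tight U-shapes.
#'
#' @param apex_angle_deg target fibre apex (bending) angle in degrees.
#' @param arm_length_mm length of each fibre arm (bank traversal), mm.
#' @param tip_radius_mm rounding radius of the fibre apex, mm.
#' @param extent_ap_mm anterior--posterior extent of the fold, mm.
#' @param cortical_thickness_mm white-to-pial distance, mm.
#' @param depth_mm depth of the fibre sheet below the white surface, mm.
#' @param arm_frac_range range of the V1-side arm length as a fraction of
#'   `arm_length_mm` (uniform per fibre); spreads the V1 terminations
#'   across the bank so the cross-fold (polar-angle) topography is
#'   non-degenerate.  The apex angle is unaffected.
#' @param n_fibres number of V1--V2 connecting fibres.
#' @param n_nonconnecting additional single-bank fibres that stop well
#'   short of the apex and so do not connect V1 and V2 (default 0).
#' @param mode `"sheet"` (fold-following fibres) or `"bundle"` (straight
#'   fibres in a tube along the fold axis).
#' @param jitter_pos_sd_mm per-fibre rigid positional jitter sd, mm.
#' @param jitter_ang_sd_deg per-fibre in-plane angular jitter sd, degrees.
#' @param fibre_step_mm sampling step along fibres, mm.
#' @param mesh_step_mm mesh sampling step (both directions), mm.
#' @param arm_margin_mm extra bank length of the surfaces beyond the fibre
#'   arms, mm (keeps fibre endpoints away from the mesh border).
#' @param ecc_range_deg eccentricity range over the A--P extent, degrees.
#' @param polar_range_deg polar-angle range across the fold, degrees.
#' @param stim_freq stimulus frequency, cycles per run.
#' @param n_samples fMRI samples per run.
#' @param tr_s sampling interval, seconds.
#' @param amplitude,baseline,noise_sd response amplitude, baseline and
#'   additive Gaussian noise sd (arbitrary units).
#' @param n_bands_ecc,n_bands_polar topographic band counts (6 and 15).
#' @param seed integer RNG seed; a fixed seed makes every artefact of the
#'   scene reproducible.
#' @return a list with class `"scene_config"`.
#' @export
scene_config <- function(apex_angle_deg = 140,
                         arm_length_mm = 10,
                         tip_radius_mm = 0.3,
                         arm_frac_range = c(0.6, 1),
                         extent_ap_mm = 30,
                         cortical_thickness_mm = 2.5,
                         depth_mm = 0.5,
                         n_fibres = 200,
                         n_nonconnecting = 0,
                         mode = c("sheet", "bundle"),
                         jitter_pos_sd_mm = 0.5,
                         jitter_ang_sd_deg = 2,
                         fibre_step_mm = 0.2,
                         mesh_step_mm = 0.6,
                         arm_margin_mm = 4,
                         ecc_range_deg = c(3, 6.9),
                         polar_range_deg = c(90, 270),
                         stim_freq = 8,
                         n_samples = 128,
                         tr_s = 2,
                         amplitude = 1,
                         baseline = 100,
                         noise_sd = 0.2,
                         n_bands_ecc = 6,
                         n_bands_polar = 15,
                         seed = 1) {
  mode <- match.arg(mode)
  stopifnot(apex_angle_deg > 0, apex_angle_deg < 180,
            arm_length_mm > 0, tip_radius_mm > 0, extent_ap_mm > 0,
            cortical_thickness_mm > 0, depth_mm > 0,
            n_fibres >= 1, n_nonconnecting >= 0,
            length(arm_frac_range) == 2, arm_frac_range[1] > 0,
            arm_frac_range[1] <= arm_frac_range[2], arm_frac_range[2] <= 1,
            jitter_pos_sd_mm >= 0, jitter_ang_sd_deg >= 0,
            fibre_step_mm > 0, mesh_step_mm > 0, arm_margin_mm >= 0,
            length(ecc_range_deg) == 2, ecc_range_deg[1] >= 0,
            diff(ecc_range_deg) > 0,
            stim_freq >= 1, n_samples >= 4 * stim_freq,
            amplitude >= 0, noise_sd >= 0)
  cfg <- as.list(environment())
  structure(cfg, class = "scene_config")
}

# cross-section of the fold in the x-z plane: two straight arms at apex
# angle `theta` joined by a tangent circular tip of radius `r`; returns
# points and outward unit normals at uniform arc-length samples `s`
# (s = 0 at the left arm end, increasing to the right)
xsec_eval <- function(s, theta_deg, arm, r) {
  phi <- deg2rad(theta_deg / 2)
  arc_len <- r * (pi - 2 * phi)
  total <- 2 * arm + arc_len
  dminus <- c(-sin(phi), -cos(phi))              # left arm direction (outward-down)
  dplus <- c(sin(phi), -cos(phi))
  p_minus <- r * c(cos(pi - phi), sin(pi - phi)) # left junction
  p_plus <- r * c(cos(phi), sin(phi))

  x <- numeric(length(s)); z <- numeric(length(s))
  nx <- numeric(length(s)); nz <- numeric(length(s))
  left <- s <= arm
  tip <- s > arm & s < arm + arc_len
  right <- s >= arm + arc_len
  # left arm: from the arm end towards the junction
  x[left] <- p_minus[1] + (arm - s[left]) * dminus[1]
  z[left] <- p_minus[2] + (arm - s[left]) * dminus[2]
  nx[left] <- -cos(phi); nz[left] <- sin(phi)
  # tip arc
  a <- (pi - phi) - (s[tip] - arm) / r
  x[tip] <- r * cos(a); z[tip] <- r * sin(a)
  nx[tip] <- cos(a); nz[tip] <- sin(a)
  # right arm
  t <- s[right] - arm - arc_len
  x[right] <- p_plus[1] + t * dplus[1]
  z[right] <- p_plus[2] + t * dplus[2]
  nx[right] <- cos(phi); nz[right] <- sin(phi)
  list(x = x, z = z, nx = nx, nz = nz, total = total, arc_len = arc_len,
       s_apex = arm + arc_len / 2)
}

#' Generate the folded white and pial surfaces of the phantom
#'
#' Extrudes the fold cross-section along the anterior--posterior axis.
#' The white surface is the fibre cross-section offset outward by the
#' fibre depth; the pial surface is offset further by the cortical
#' thickness, so the white/pial separation equals the thickness
#' everywhere and the cortical ribbon is well defined.  Triangle winding
#' makes the normals point outward (from white matter towards CSF).  The
#' returned meshes carry per-vertex attributes `xsec_s` (cross-fold arc
#' length) and `ap_y` (anterior--posterior coordinate) used by the
#' retinotopic field generator.
#'
#' @param cfg a [scene_config()].
#' @return list with elements `white` and `pial` ([surface_mesh()]es).
#' @export
make_gyrus_mesh <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  build_one <- function(r_tip, role) {
    arm <- cfg$arm_length_mm + cfg$arm_margin_mm
    probe <- xsec_eval(0, cfg$apex_angle_deg, arm, r_tip)
    ns <- max(2L, ceiling(probe$total / cfg$mesh_step_mm) + 1L)
    s <- seq(0, probe$total, length.out = ns)
    cs <- xsec_eval(s, cfg$apex_angle_deg, arm, r_tip)
    ys <- seq(0, cfg$extent_ap_mm,
              length.out = max(2L, ceiling(cfg$extent_ap_mm / cfg$mesh_step_mm) + 1L))
    ny <- length(ys)
    v <- cbind(rep(cs$x, ny), rep(ys, each = ns), rep(cs$z, ny))
    idx <- function(i, j) (j - 1L) * ns + i
    i <- rep(seq_len(ns - 1L), ny - 1L)
    j <- rep(seq_len(ny - 1L), each = ns - 1L)
    f <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
               cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
    mesh <- surface_mesh(v, f, role = role)
    attr(mesh, "xsec_s") <- rep(s, ny)
    attr(mesh, "ap_y") <- v[, 2]
    mesh
  }
  r_white <- cfg$tip_radius_mm + cfg$depth_mm
  r_pial <- r_white + cfg$cortical_thickness_mm
  if (r_pial <= r_white) abort("cortical thickness must be positive")
  list(white = build_one(r_white, "white"),
       pial = build_one(r_pial, "pial"))
}

# rotation about the y axis by `ang` radians, around a pivot point
rotate_xz <- function(pts, ang, pivot) {
  cc <- sweep(pts, 2, pivot)
  out <- cc
  out[, 1] <- cos(ang) * cc[, 1] + sin(ang) * cc[, 3]
  out[, 3] <- -sin(ang) * cc[, 1] + cos(ang) * cc[, 3]
  sweep(out, 2, pivot, `+`)
}

#' Generate the phantom SAF streamlines and ground-truth manifest
#'
#' In `"sheet"` mode each fibre follows the fold cross-section at a fixed
#' depth below the white surface at a random anterior--posterior station,
#' with optional per-fibre rigid positional jitter and in-plane angular
#' jitter about its apex.  In `"bundle"` mode fibres are straight lines
#' along the fold axis within a narrow tube.  The manifest records, per
#' streamline, the seeded station, analytic apex angle and arc length,
#' seed retinotopy, eccentricity band, depth, and whether the fibre was
#' planted to connect V1 and V2.
#'
#' @param cfg a [scene_config()].
#' @param white the white [surface_mesh()] from [make_gyrus_mesh()]
#'   (used for consistency checks).
#' @return list with elements `tract` ([tractogram()]) and `manifest`
#'   (tibble, one row per streamline).
#' @export
make_saf_streamlines <- function(cfg, white = NULL) {
  stopifnot(inherits(cfg, "scene_config"))
  if (cfg$depth_mm >= cfg$arm_length_mm * cos(deg2rad(cfg$apex_angle_deg / 2))) {
    abort("fibre depth reaches beyond the available white matter under the fold")
  }
  margin <- 1
  n_total <- cfg$n_fibres + cfg$n_nonconnecting
  ys <- stats::runif(n_total, margin, cfg$extent_ap_mm - margin)
  arm_fracs <- stats::runif(n_total, cfg$arm_frac_range[1], cfg$arm_frac_range[2])
  band_br <- seq(0, cfg$extent_ap_mm, length.out = cfg$n_bands_ecc + 1L)
  ecc_of <- function(y) cfg$ecc_range_deg[1] +
    (y / cfg$extent_ap_mm) * diff(cfg$ecc_range_deg)
  # white-surface cross-fold coordinate of the fibre's V1-side endpoint
  polar_of_s <- function(s_w, total_w) cfg$polar_range_deg[1] +
    (s_w / total_w) * diff(cfg$polar_range_deg)
  probe_w <- xsec_eval(0, cfg$apex_angle_deg,
                       cfg$arm_length_mm + cfg$arm_margin_mm,
                       cfg$tip_radius_mm + cfg$depth_mm)

  streamlines <- vector("list", n_total)
  rows <- vector("list", n_total)
  for (k in seq_len(n_total)) {
    connecting <- k <= cfg$n_fibres
    arm_v1 <- NA_real_; s0 <- NA_real_
    if (cfg$mode == "bundle") {
      zc <- stats::rnorm(1, -3, 1); xc <- stats::rnorm(1, 0, 1)
      s <- seq(0, cfg$extent_ap_mm - 2 * margin, by = cfg$fibre_step_mm)
      pts <- cbind(xc, margin + s, zc)
      apex_idx <- which.min(abs(s - max(s) / 2))
    } else {
      probe <- xsec_eval(0, cfg$apex_angle_deg, cfg$arm_length_mm, cfg$tip_radius_mm)
      arm_v1 <- arm_fracs[k] * cfg$arm_length_mm
      s0 <- cfg$arm_length_mm - arm_v1        # shortened V1 (left) arm
      # non-connecting fibres stop 4 mm short of the apex so their V2-side
      # end stays beyond the default nearest-vertex selection tolerance
      s_end <- if (connecting) probe$total else
        max(s0 + 2 * cfg$fibre_step_mm, probe$s_apex - 4)
      s <- sort(unique(c(seq(s0, s_end, by = cfg$fibre_step_mm), probe$s_apex, s_end)))
      s <- s[s >= s0 - 1e-9 & s <= s_end + 1e-9]
      cs <- xsec_eval(s, cfg$apex_angle_deg, cfg$arm_length_mm, cfg$tip_radius_mm)
      # place the fibre depth_mm below the white surface: the white
      # cross-section is this curve offset outward by depth_mm
      pts <- cbind(cs$x, ys[k], cs$z)
      apex_idx <- which.min(abs(s - probe$s_apex))
      if (cfg$jitter_ang_sd_deg > 0) {
        ang <- deg2rad(stats::rnorm(1, 0, cfg$jitter_ang_sd_deg))
        pts <- rotate_xz(pts, ang, pts[apex_idx, ])
      }
    }
    if (cfg$jitter_pos_sd_mm > 0) {
      pts <- sweep(pts, 2, stats::rnorm(3, 0, cfg$jitter_pos_sd_mm), `+`)
    }
    streamlines[[k]] <- pts
    e1 <- pts[1, ]; e2 <- pts[nrow(pts), ]; ap <- pts[apex_idx, ]
    true_angle <- vec_angle_deg(ap - e1, ap - e2)
    rows[[k]] <- tibble::tibble(
      streamline = k,
      y_seed = ys[k],
      true_length = sum(row_norms(diff(pts))),
      true_apex_angle = true_angle,
      seed_eccentricity = ecc_of(ys[k]),
      seed_polar_angle = if (cfg$mode == "sheet")
        wrap_degrees(polar_of_s(cfg$arm_margin_mm + s0, probe_w$total)) else NA_real_,
      arm_v1_mm = arm_v1,
      band_ecc = pmin(findInterval(ys[k], band_br, rightmost.closed = TRUE),
                      cfg$n_bands_ecc),
      depth = cfg$depth_mm,
      connecting = connecting)
  }
  list(tract = tractogram(streamlines), manifest = dplyr::bind_rows(rows))
}

#' Generate smooth retinotopic fields on a phantom mesh
#'
#' Eccentricity is linear in the anterior--posterior coordinate over the
#' configured range; polar angle is linear in the cross-fold arc-length
#' coordinate.  Requires the per-vertex coordinates that
#' [make_gyrus_mesh()] attaches to its meshes.
#'
#' @param cfg a [scene_config()].
#' @param mesh a phantom [surface_mesh()] carrying `xsec_s` and `ap_y`
#'   attributes.
#' @return list with `eccentricity` and `polar_angle`
#'   [vertex_scalar_map()]s.
#' @export
make_retinotopy_fields <- function(cfg, mesh) {
  ys <- attr(mesh, "ap_y")
  ss <- attr(mesh, "xsec_s")
  if (is.null(ys) || is.null(ss)) {
    abort("mesh does not carry phantom coordinates (ap_y / xsec_s)")
  }
  ecc <- cfg$ecc_range_deg[1] + (ys / cfg$extent_ap_mm) * diff(cfg$ecc_range_deg)
  pol <- cfg$polar_range_deg[1] + (ss / max(ss)) * diff(cfg$polar_range_deg)
  list(eccentricity = vertex_scalar_map(ecc, kind = "eccentricity"),
       polar_angle = vertex_scalar_map(wrap_degrees(pol), kind = "polar_angle"))
}

#' Generate phase-encoded fMRI time series on a phantom mesh
#'
#' Per vertex: `baseline + amplitude * sin(2*pi*f*t/T + phase) + noise`,
#' where the phase encodes the vertex's retinotopic coordinate (linear
#' map of the supplied field onto `[0, 2*pi)`), `f` is the stimulus
#' frequency in cycles per run and the noise is i.i.d. Gaussian.
#'
#' @param cfg a [scene_config()].
#' @param map the [vertex_scalar_map()] whose values the phase encodes
#'   (typically eccentricity).
#' @param mesh the carrying mesh (vertex count check).
#' @return an [fmri_timeseries()]; the planted per-vertex phase (radians)
#'   is attached as attribute `phase`.
#' @export
make_fmri_timeseries <- function(cfg, map, mesh) {
  if (length(map) != n_vertices(mesh)) abort("map is not bound to this mesh")
  vals <- map$values
  rng <- range(vals)
  phase <- if (diff(rng) > 0) 2 * pi * (vals - rng[1]) / diff(rng) else rep(0, length(vals))
  T <- cfg$n_samples
  tt <- seq_len(T) - 1L
  clean <- cfg$baseline +
    cfg$amplitude * sin(outer(phase, 2 * pi * cfg$stim_freq * tt / T, `+`))
  noise <- matrix(stats::rnorm(length(clean), 0, cfg$noise_sd), nrow = nrow(clean))
  ts <- fmri_timeseries(clean + noise,
                        stimulus_frequency = cfg$stim_freq, tr = cfg$tr_s)
  attr(ts, "phase") <- phase
  ts
}

#' Generate a complete phantom scene
#'
#' Runs the mesh, streamline, retinotopy and fMRI generators under one
#' seed and adds surface V1/V2 labels (left and right bank of the fold,
#' split at the apex).  A fixed seed makes the scene fully reproducible.
#'
#' @param cfg a [scene_config()].
#' @return a `"saf_scene"` list: `config`, `white`, `pial`, `tract`,
#'   `manifest`, `eccentricity`, `polar_angle`, `v1`, `v2`, `fmri`.
#' @examples
#' scene <- simulate_scene(scene_config(n_fibres = 20, seed = 7))
#' scene$tract
#' @export
simulate_scene <- function(cfg = scene_config()) {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(cfg$seed, {
    meshes <- make_gyrus_mesh(cfg)
    fib <- make_saf_streamlines(cfg, meshes$white)
    fields <- make_retinotopy_fields(cfg, meshes$white)
    fmri <- make_fmri_timeseries(cfg, fields$eccentricity, meshes$white)
    vx <- meshes$white$vertices[, 1]
    v1 <- cortical_label("V1", vertices = which(vx < 0))
    v2 <- cortical_label("V2", vertices = which(vx >= 0))
    structure(list(config = cfg,
                   white = meshes$white, pial = meshes$pial,
                   tract = fib$tract, manifest = fib$manifest,
                   eccentricity = fields$eccentricity,
                   polar_angle = fields$polar_angle,
                   v1 = v1, v2 = v2, fmri = fmri),
              class = "saf_scene")
  })
}

#' @export
print.saf_scene <- function(x, ...) {
  cat(sprintf("<saf_scene mode=%s> %d fibres, fold extent %g mm, apex %g deg, seed %d\n",
              x$config$mode, length(x$tract), x$config$extent_ap_mm,
              x$config$apex_angle_deg, x$config$seed))
  invisible(x)
}

#' Variance-controlled streamline phantom
#'
#' Generates straight-segment streamlines whose pooled point coordinates
#' have exactly the requested per-axis variances (mm^2) in a known frame:
#' segment centres are Gaussian, rescaled to the exact target variance,
#' with the within-segment spread along the first axis accounted for
#' analytically.  Useful for validating [sheet_sizes()] and
#' [sheet_frame()] recovery, optionally under a rotation.
#'
#' @param sizes target per-axis variances (mm^2), descending.
#' @param n number of streamlines.
#' @param pts points per streamline.
#' @param segment_length streamline length along the first axis, mm.
#' @param rotation optional 3 x 3 rotation applied to the cloud.
#' @param seed RNG seed.
#' @return list with `tract` ([tractogram()]), `sizes` (the exact planted
#'   variances) and `frame` (the planted axes, columns).
#' @export
make_variance_phantom <- function(sizes = c(25, 9, 1), n = 200, pts = 50,
                                  segment_length = 10, rotation = NULL,
                                  seed = 1) {
  stopifnot(length(sizes) == 3, all(sizes > 0), !is.unsorted(rev(sizes)))
  offs <- seq(-segment_length / 2, segment_length / 2, length.out = pts)
  within <- mean((offs - mean(offs))^2)
  if (within >= sizes[1]) abort("segment too long for the first-axis variance target")
  targets <- c(sizes[1] - within, sizes[2], sizes[3])
  with_seed(seed, {
    centres <- matrix(stats::rnorm(3 * n), n, 3)
    for (k in 1:3) {
      ck <- centres[, k] - mean(centres[, k])
      centres[, k] <- ck / sqrt(mean(ck^2)) * sqrt(targets[k])
    }
    rot <- rotation %||% diag(3)
    streamlines <- lapply(seq_len(n), function(i) {
      seg <- cbind(centres[i, 1] + offs, centres[i, 2], centres[i, 3])
      seg %*% t(rot)
    })
    list(tract = tractogram(streamlines), sizes = sizes, frame = rot)
  })
}

#' Write a phantom scene to a directory of plain files
#'
#' Writes the tractogram (TCK), surfaces (OFF), retinotopic maps
#' (one value per line), surface labels (one vertex index per line) and
#' the ground-truth manifest (TSV).
#'
#' @param scene a `"saf_scene"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "saf_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tractogram(scene$tract, file.path(dir, "saf.tck"))
  write_surface_off(scene$white, file.path(dir, "white.off"))
  write_surface_off(scene$pial, file.path(dir, "pial.off"))
  write_vertex_map(scene$eccentricity, file.path(dir, "eccentricity.txt"))
  write_vertex_map(scene$polar_angle, file.path(dir, "polar_angle.txt"))
  writeLines(as.character(scene$v1$vertices), file.path(dir, "v1_vertices.txt"))
  writeLines(as.character(scene$v2$vertices), file.path(dir, "v2_vertices.txt"))
  write_report(scene$manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}
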