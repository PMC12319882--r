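test_that("a fixed seed reproduces the scene; different seeds differ", {
  cfg <- scene_config(n_fibres = 10, seed = 21)
  a <- simulate_scene(cfg)
  b <- simulate_scene(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$tract$streamlines, b$tract$streamlines)
  c <- simulate_scene(scene_config(n_fibres = 10, seed = 22))
  expect_false(identical(a$manifest$y_seed, c$manifest$y_seed))
})

test_that("scene generation does not disturb the caller's RNG stream", {
  set.seed(5)
  expected <- rnorm(3)
  set.seed(5)
  invisible(simulate_scene(scene_config(n_fibres = 5, seed = 9)))
  expect_identical(rnorm(3), expected)
})

test_that("the manifest records the planted geometry", {
  sc <- simulate_scene(scene_config(n_fibres = 25, n_nonconnecting = 5,
                                    jitter_pos_sd_mm = 0,
                                    jitter_ang_sd_deg = 0, seed = 31))
  m <- sc$manifest
  expect_equal(nrow(m), 30)
  expect_equal(sum(m$connecting), 25)
  expect_equal(m$true_length,
               vapply(sc$tract$streamlines, arc_length, numeric(1)))
  # without jitter the planted apex angle is the configured one
  expect_lt(max(abs(m$true_apex_angle[m$connecting] - 140)), 2)
  expect_true(all(m$y_seed > 0 & m$y_seed < 30))
  expect_true(all(m$band_ecc %in% 1:6))
})

test_that("the phantom ribbon has the configured thickness and fibre depth", {
  cfg <- scene_config(n_fibres = 10, jitter_pos_sd_mm = 0,
                      jitter_ang_sd_deg = 0, seed = 41)
  sc <- simulate_scene(cfg)
  # white-to-pial distance equals the cortical thickness away from the
  # mesh borders (discretisation of the rounded tip allows a small slack)
  ss <- attr(sc$white, "xsec_s")
  interior <- which(abs(attr(sc$white, "ap_y") - 15) < 5 &
                      ss > 5 & ss < max(ss) - 5)
  interior <- interior[seq(1, length(interior), by = 37)]
  d <- closest_point_on_mesh(sc$white$vertices[interior, ], sc$pial)
  expect_lt(max(abs(d$dist - cfg$cortical_thickness_mm)), 0.1)
  expect_true(all(d$signed_dist < 0))          # white lies under the pial
  # fibre points sit at the planted depth below the white surface
  pts <- sc$tract$streamlines[[1]]
  pts <- pts[seq(1, nrow(pts), by = 12), ]
  dw <- closest_point_on_mesh(pts, sc$white)
  expect_lt(max(abs(dw$signed_dist + cfg$depth_mm)), 0.1)
  expect_true(all(dw$signed_dist < 0))         # fibres lie under the white
})

test_that("retinotopic fields span the configured ranges smoothly", {
  cfg <- scene_config(n_fibres = 5, seed = 51)
  sc <- simulate_scene(cfg)
  expect_equal(range(sc$eccentricity$values), cfg$ecc_range_deg,
               tolerance = 1e-8)
  expect_identical(sc$polar_angle$kind, "polar_angle")
  # eccentricity is a function of the anterior-posterior coordinate only
  ys <- attr(sc$white, "ap_y")
  fit <- lm(sc$eccentricity$values ~ ys)
  expect_lt(sqrt(mean(residuals(fit)^2)), 1e-10)
})

test_that("phase-encoded responses are detectable exactly when modulated", {
  cfg <- scene_config(n_fibres = 5, noise_sd = 0.05, seed = 61)
  sc <- simulate_scene(cfg)
  snr <- compute_snr(sc$fmri)
  expect_true(all(reliable_mask(snr)))
  # with the modulation switched off nothing survives the threshold
  flat_cfg <- scene_config(n_fibres = 5, amplitude = 0, noise_sd = 0.05,
                           seed = 61)
  flat <- simulate_scene(flat_cfg)
  expect_true(mean(reliable_mask(compute_snr(flat$fmri))) < 0.05)
})

test_that("bundle mode plants a tube along the fold axis", {
  sc <- simulate_scene(scene_config(n_fibres = 30, mode = "bundle",
                                    seed = 71))
  sizes <- sheet_sizes(sc$tract, sheet_frame(sc$tract))
  expect_identical(classify_geometry(as.numeric(sizes)), "bundle")
})

test_that("variance phantom rejects an over-long segment", {
  expect_error(make_variance_phantom(c(4, 2, 1), segment_length = 10),
               "segment too long")
})

test_that("a scene round-trips through its plain-file representation", {
  sc <- simulate_scene(scene_config(n_fibres = 6, seed = 81))
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  t2 <- read_tractogram(file.path(dir, "saf.tck"))
  expect_length(t2, 6)
  expect_equal(t2$streamlines[[3]], unclass(sc$tract$streamlines[[3]]),
               tolerance = 1e-6, ignore_attr = TRUE)
  w2 <- read_surface_off(file.path(dir, "white.off"), role = "white")
  expect_equal(w2$vertices, sc$white$vertices)
  e2 <- read_vertex_map(file.path(dir, "eccentricity.txt"), "eccentricity")
  expect_equal(e2$values, sc$eccentricity$values)
  m2 <- read_report(file.path(dir, "manifest.tsv"))
  expect_equal(m2$true_length, sc$manifest$true_length)
  v1v <- as.integer(readLines(file.path(dir, "v1_vertices.txt")))
  expect_equal(v1v, sc$v1$vertices)
})
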