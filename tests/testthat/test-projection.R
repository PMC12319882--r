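# A tiny flat scene with analytic maps: white surface at z = 0, vertex
# eccentricity linear in y, polar angle linear in x, V1 = x < 0, V2 = x >= 0.
flat_scene <- function(step = 2) {
  mesh <- flat_mesh(z = 0, step = step)
  ecc <- vertex_scalar_map(3 + 0.1 * mesh$vertices[, 2], kind = "eccentricity")
  pol <- vertex_scalar_map(180 + 2 * mesh$vertices[, 1], kind = "polar_angle")
  labs <- split_labels(mesh)
  list(mesh = mesh, ecc = ecc, pol = pol, v1 = labs$v1, v2 = labs$v2)
}

test_that("endpoint_vertices finds the surrounding triangle and weights", {
  sc <- flat_scene()
  ev <- endpoint_vertices(c(-10, 10, 0.5), sc$mesh, tol = 2)
  expect_true(ev$ok)
  expect_equal(ev$dist, 0.5)
  expect_equal(sum(ev$weights), 1)
  expect_true(all(ev$weights >= -1e-9))
  # the three surrounding vertices enclose the projected point
  vv <- sc$mesh$vertices[ev$vertices, ]
  expect_equal(colSums(vv * ev$weights), c(-10, 10, 0), ignore_attr = TRUE)
  far <- endpoint_vertices(c(0, 10, 5), sc$mesh, tol = 2)
  expect_false(far$ok)
})

test_that("projection carries four retinotopy values per streamline", {
  sc <- flat_scene()
  t <- tractogram(list(
    rbind(c(-10, 6, -0.5), c(0, 6, -2), c(10, 6, -0.5)),
    rbind(c(-8, 14, -0.5), c(0, 14, -2), c(8, 14, -0.5))))
  pr <- project_retinotopy(t, sc$mesh, sc$ecc, sc$pol, sc$v1, sc$v2)
  expect_equal(nrow(pr$streamlines), 2)
  expect_equal(nrow(pr$endpoints), 4)          # two endpoints per streamline
  # four values per streamline: an eccentricity and polar angle per endpoint
  per <- dplyr::count(pr$endpoints, streamline)
  expect_true(all(per$n == 2))
  expect_true(all(is.finite(pr$endpoints$mean_eccentricity)))
  expect_true(all(is.finite(pr$endpoints$mean_polar_angle)))
  expect_true(all(pr$streamlines$v2_in_v2))
  expect_false(any(pr$streamlines$unvalued))
  # the carried value is the unweighted mean over the V1-end's three
  # surrounding vertices, circular for polar angle
  v1_ends <- dplyr::filter(pr$endpoints, end == "V1")
  for (r in seq_len(nrow(v1_ends))) {
    vs <- unlist(v1_ends[r, c("vertex1", "vertex2", "vertex3")])
    expect_equal(v1_ends$mean_eccentricity[r], mean(sc$ecc$values[vs]))
    expect_equal(v1_ends$mean_polar_angle[r],
                 circular_mean_deg(sc$pol$values[vs]))
  }
  expect_equal(pr$streamlines$projected_eccentricity,
               v1_ends$mean_eccentricity)
  expect_equal(pr$streamlines$v1_end_x, c(-10, -8))
})

test_that("off-surface and ambiguous streamlines are dropped with reasons", {
  sc <- flat_scene()
  t <- tractogram(list(
    rbind(c(-10, 6, -0.5), c(10, 6, -0.5)),     # fine
    rbind(c(-10, 8, 5), c(10, 8, -0.5)),        # first endpoint 5 mm off
    rbind(c(-10, 10, -0.5), c(-6, 10, -0.5))))  # both endpoints in V1
  pr <- project_retinotopy(t, sc$mesh, sc$ecc, sc$pol, sc$v1, sc$v2)
  expect_equal(pr$streamlines$streamline, 1L)
  expect_equal(sort(pr$dropped$streamline), c(2L, 3L))
  expect_setequal(pr$dropped$reason, c("off_surface", "ambiguous_v1_end"))
  expect_error(project_retinotopy(t, sc$mesh, sc$ecc, sc$pol, sc$v1, sc$v2,
                                  projection_params(strict = TRUE)),
               "V1-side endpoint")
})

test_that("projection refuses overlapping labels and unbound maps", {
  sc <- flat_scene()
  both <- cortical_label("V1", vertices = c(sc$v1$vertices, sc$v2$vertices[1]))
  t <- tractogram(list(rbind(c(-10, 6, -0.5), c(10, 6, -0.5))))
  expect_error(project_retinotopy(t, sc$mesh, sc$ecc, sc$pol, both, sc$v2),
               "overlap")
  short_map <- vertex_scalar_map(1:4, kind = "eccentricity")
  expect_error(project_retinotopy(t, sc$mesh, short_map, sc$pol, sc$v1, sc$v2),
               "not bound")
})

test_that("endpoints on unvalued map vertices flag the streamline", {
  sc <- flat_scene()
  vals <- sc$ecc$values
  near <- which(sc$mesh$vertices[, 1] <= -8)   # invalidate the V1 endpoint area
  vals[near] <- NA
  ecc_holes <- vertex_scalar_map(vals, kind = "eccentricity")
  t <- tractogram(list(rbind(c(-10, 6, -0.5), c(10, 6, -0.5))))
  pr <- project_retinotopy(t, sc$mesh, ecc_holes, sc$pol, sc$v1, sc$v2)
  expect_true(pr$streamlines$unvalued[1])
  expect_true(is.na(pr$streamlines$projected_eccentricity[1]))
})

test_that("band labels partition the extent into equal contiguous bands", {
  b <- band_labels(c(0, 30), 6, "eccentricity")
  expect_equal(nrow(b), 6)
  expect_equal(b$hi - b$lo, rep(5, 6))
  expect_equal(b$lo[-1], b$hi[-6])             # contiguous, non-overlapping
  expect_error(band_labels(c(3, 3), 4), "degenerate")
  expect_error(band_labels(c(0, 1), 1), "at least 2")
})

test_that("vertex-path bands split a path by arc length into a partition", {
  mesh <- flat_mesh(step = 2)
  path <- which(mesh$vertices[, 2] == 10)       # a straight row of vertices
  path <- path[order(mesh$vertices[path, 1])]
  b <- band_labels(path, 3, "polar_angle", mesh = mesh)
  got <- sort(unlist(b$vertices))
  expect_equal(got, sort(path))                 # disjoint cover of the path
  expect_equal(lengths(b$vertices), c(7, 7, 7))
})

test_that("band clustering assigns streamlines to the planted bands", {
  proj <- tibble::tibble(streamline = 1:5,
                         v1_end_x = 0, v1_end_y = c(1, 7, 14, 26, 40),
                         v1_end_z = 0)
  bands <- band_labels(c(0, 30), 6, "eccentricity")
  expect_message(cl <- cluster_by_band(proj, bands), "outside all bands")
  expect_equal(cl$cluster, c(1L, 2L, 3L, 6L, NA))
  expect_s3_class(cl, "saf_clustering")
  expect_s3_class(autoplot(cl), "ggplot")
})

test_that("the order index is exact on monotone, reversed and wrapped data", {
  pos <- seq(0, 10, length.out = 20)
  expect_equal(topographic_order_index(exp(pos / 5), pos), 1)
  expect_equal(topographic_order_index(rev(exp(pos / 5)), pos), -1)
  # circular values marching through the 0/360 wrap stay perfectly ordered
  ang <- wrap_degrees(seq(300, 420, length.out = 20))
  expect_equal(topographic_order_index(ang, pos, circular = TRUE), 1)
  expect_warning(oi <- topographic_order_index(rep(1, 10), pos[1:10]),
                 "constant")
  expect_equal(oi, 0)
  expect_error(topographic_order_index(1:2, 1:2), "at least 3")
})
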