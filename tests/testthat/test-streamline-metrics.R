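test_that("arc_length sums segment lengths exactly", {
  s <- streamline(rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12)))
  expect_equal(arc_length(s), 5 + 12)
})

test_that("resampling is uniform with exact endpoints", {
  s <- streamline(rbind(c(0, 0, 0), c(2, 0, 0), c(2, 3, 0), c(2, 3, 7)))
  r <- resample_streamline(s, 0.5)
  expect_equal(r[1, ], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(r[nrow(r), ], c(2, 3, 7), ignore_attr = TRUE)
  seg <- sqrt(rowSums(diff(unclass(r))^2))
  expect_lt(max(seg) - min(seg), 1e-9)        # strictly uniform spacing
  expect_lte(max(seg), 0.5 + 1e-9)
  expect_equal(sum(seg), 12)                  # a straight-segment polyline
                                              # keeps its length exactly
})

test_that("a step at or beyond the length collapses to the endpoints", {
  s <- streamline(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  r <- resample_streamline(s, 10)
  expect_equal(nrow(r), 2)
  expect_error(resample_streamline(s, 0), "positive")
})

test_that("circular-arc bending angles match the inscribed-angle theorem", {
  # for an arc subtending 2a at the centre, the angle apex-to-endpoints
  # is 180 - a degrees (isosceles triangle at the apex)
  for (a_deg in c(30, 60, 90)) {
    a <- a_deg * pi / 180
    th <- seq(pi / 2 - a, pi / 2 + a, length.out = 301)
    s <- streamline(cbind(10 * cos(th), 10 * sin(th), 0))
    got <- apex_and_bending_angle(s)
    expect_equal(got$bending_angle, 180 - a_deg, tolerance = 0.5)
    # on a constant-curvature arc every point is a legitimate apex, so the
    # tie-break only guarantees a point on the arc near its middle
    expect_equal(sqrt(sum(got$apex_position^2)), 10, tolerance = 0.01)
    expect_lt(abs(got$apex_position[1]), 1.5)
  }
})

test_that("bending angle survives coordinate noise on a V-shape", {
  set.seed(11)
  s <- v_polyline(120, arm = 10, step = 0.2)
  noisy <- streamline(unclass(s) + matrix(rnorm(length(s), sd = 0.05),
                                          ncol = 3))
  got <- apex_and_bending_angle(noisy)
  expect_equal(got$bending_angle, 120, tolerance = 5)
})

test_that("degenerate streamlines are flagged instead of crashing", {
  s <- streamline(rbind(c(0, 0, 0), c(0.1, 0, 0)))
  got <- apex_and_bending_angle(s, selection_params())
  expect_true(got$degenerate)
  expect_true(is.na(got$bending_angle))
})

test_that("intracortical fraction of a half-in-ribbon line is one half", {
  white <- flat_mesh(z = 0, role = "white")
  pial <- flat_mesh(z = 2.5, role = "pial")
  # spans z in [-2.5, 2.5]: exactly half its arc length is in the ribbon
  s <- vertical_streamline(0, 10, -2.5, 2.5)
  expect_equal(intracortical_fraction(s, white, pial, step = 0.05), 0.5,
               tolerance = 0.02)
  # fully inside and fully below
  expect_equal(intracortical_fraction(streamline(cbind(c(-5, 5), 10, 1)),
                                      white, pial, step = 0.05), 1)
  expect_equal(intracortical_fraction(streamline(cbind(c(-5, 5), 10, -1)),
                                      white, pial, step = 0.05), 0)
})

test_that("a swapped ribbon is rejected", {
  white <- flat_mesh(z = 0, role = "white")
  pial <- flat_mesh(z = 2.5, role = "pial")
  expect_error(intracortical_fraction(vertical_streamline(0, 10, -1, 1),
                                      pial, white), "ribbon")
})

test_that("length filter keeps the closed interval [min, max]", {
  lens <- c(2, 3, 50, 120, 121)
  t <- tractogram(lapply(lens, function(L) cbind(c(0, L), 0, 0)))
  out <- length_filter(t, selection_params("invivo"))
  expect_equal(unname(attr(out, "counts")), c(5, 3, 2))
  expect_equal(vapply(out$streamlines, arc_length, numeric(1)), c(3, 50, 120))
  pm <- length_filter(t, selection_params("postmortem"))   # 3-30 mm window
  expect_equal(vapply(pm$streamlines, arc_length, numeric(1)), 3)
})

test_that("deep white-matter exclusion removes only diving streamlines", {
  white <- flat_mesh(z = 0, role = "white")
  t <- tractogram(list(
    cbind(c(-5, 5), 10, -1),                        # shallow: kept
    cbind(c(-5, 0, 5), c(10, 10, 10), c(-1, -3, -1)),  # dives to -3: removed
    cbind(c(-5, 5), 10, -1.9)))                     # just above 2 mm: kept
  out <- deep_wm_exclusion(t, white, params = selection_params(), step = 0.25)
  expect_equal(unname(attr(out, "counts")), c(3, 2, 1))
  inf <- deep_wm_exclusion(t, white, depth = Inf)
  expect_equal(unname(attr(inf, "counts")), c(3, 3, 0))
})

test_that("selection with voxel labels finds exactly the traversing set", {
  dim <- c(40L, 20L, 10L)
  affine <- rbind(c(1, 0, 0, -20), c(0, 1, 0, 0), c(0, 0, 1, -5),
                  c(0, 0, 0, 1))
  grid <- array(seq_len(prod(dim)), dim)
  v1 <- cortical_label("V1", voxels = as.vector(grid[1:10, , ]),
                       dim = dim, affine = affine)
  v2 <- cortical_label("V2", voxels = as.vector(grid[31:40, , ]),
                       dim = dim, affine = affine)
  t <- tractogram(list(
    cbind(seq(-15, 15, 1), 5, 0),   # crosses both: selected
    cbind(seq(-15, -12, 1), 5, 0),  # V1 only
    cbind(seq(-5, 5, 1), 5, 0)))    # neither
  out <- select_connecting(t, v1, v2)
  expect_equal(unname(attr(out, "counts")), c(3, 1, 2))
  expect_equal(nrow(out$streamlines[[1]]), 31)
})

test_that("streamline_geometry returns one complete row per streamline", {
  t <- tractogram(list(unclass(v_polyline(120)), cbind(c(0, 10), 0, 0)))
  g <- streamline_geometry(t)
  expect_equal(nrow(g), 2)
  expect_named(g, c("streamline", "length_mm", "bending_angle_deg",
                    "apex_index", "apex_x", "apex_y", "apex_z", "degenerate"))
  expect_equal(g$bending_angle_deg[2], 180)
  white <- flat_mesh(z = -20, role = "white")
  pial <- flat_mesh(z = -17.5, role = "pial")
  g2 <- streamline_geometry(t, white = white, pial = pial)
  expect_true("intracortical_fraction" %in% names(g2))
  expect_equal(g2$intracortical_fraction, c(0, 0))
})
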