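test_that("sheet sizes are exact on the variance-controlled phantom", {
  vp <- make_variance_phantom(c(25, 9, 1), n = 150, pts = 40, seed = 3)
  sizes <- sheet_sizes(vp$tract, vp$frame)
  expect_equal(unname(as.numeric(sizes)), c(25, 9, 1), tolerance = 1e-6)
})

test_that("the principal frame recovers a planted rotation", {
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  vp <- make_variance_phantom(c(25, 9, 1), n = 300, pts = 40,
                              rotation = R, seed = 4)
  fr <- sheet_frame(vp$tract)
  # axes match the planted ones up to sign, within a few degrees
  for (j in 1:3) {
    ang <- acos(min(1, abs(sum(fr[, j] * R[, j])))) * 180 / pi
    expect_lt(ang, 5)
  }
  sizes <- sheet_sizes(vp$tract, fr)
  expect_equal(unname(as.numeric(sizes)), c(25, 9, 1), tolerance = 0.05)
})

test_that("sizes are rigid-motion invariant and trace-conserving", {
  vp <- make_variance_phantom(c(25, 9, 1), n = 100, pts = 30, seed = 8)
  sizes <- as.numeric(sheet_sizes(vp$tract, sheet_frame(vp$tract)))
  # trace invariance: the three sizes sum to the total point variance
  pts <- safsheet:::pooled_points(vp$tract)
  total <- sum(apply(pts, 2, function(x) mean((x - mean(x))^2)))
  expect_equal(sum(sizes), total, tolerance = 1e-8)
  # rigid motion: rotate and translate the whole tractogram
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- tractogram(lapply(vp$tract$streamlines,
                             function(s) sweep(unclass(s) %*% t(R), 2,
                                               c(5, -3, 11), `+`)))
  sizes_m <- as.numeric(sheet_sizes(moved, sheet_frame(moved)))
  expect_equal(sizes_m, sizes, tolerance = 1e-8)
})

test_that("an isotropic cloud has three comparable sizes", {
  set.seed(9)
  sl <- lapply(1:300, function(i) matrix(rnorm(6, sd = 2), 2, 3))
  t <- tractogram(sl)
  sizes <- as.numeric(sheet_sizes(t, sheet_frame(t)))
  expect_true(all(abs(sizes - 4) / 4 < 0.15))
  expect_identical(classify_geometry(sizes), "indeterminate")
})

test_that("residual sd estimates planted surface noise", {
  set.seed(10)
  g <- expand.grid(u = seq(-5, 5, 0.25), v = seq(-5, 5, 0.25))
  z <- rnorm(nrow(g), sd = 0.5)
  t <- tractogram(lapply(split(seq_len(nrow(g)), g$v), function(i)
    cbind(g$u[i], g$v[i], z[i])))
  fit <- fit_sheet_surface(t, diag(3), degree = 1)
  expect_equal(fit$residual_sd, 0.5, tolerance = 0.1)
})

test_that("an anatomical frame overrides the data-driven axes", {
  vp <- make_variance_phantom(c(25, 9, 1), n = 50, pts = 20, seed = 5)
  fr <- sheet_frame(vp$tract, anatomical_frame = diag(3)[, c(2, 1, 3)])
  expect_equal(abs(fr), diag(3)[, c(2, 1, 3)], ignore_attr = TRUE)
})

test_that("a single straight streamline yields a flagged, completed frame", {
  t <- tractogram(list(cbind(seq(0, 10, 1), 0, 0)))
  expect_warning(fr <- sheet_frame(t), "rank-deficient")
  expect_true(attr(fr, "rank_deficient"))
  expect_equal(crossprod(fr), diag(3))
})

test_that("classification follows the dominance and comparability rules", {
  # the group-level size pattern from in vivo SAF populations
  expect_identical(classify_geometry(c(16, 11, 2)), "sheet")
  expect_identical(classify_geometry(c(30, 2, 1.5)), "bundle")
  expect_identical(classify_geometry(c(9, 8, 7)), "indeterminate")
  # both ratios dominant: neither a clean sheet nor a clean bundle
  expect_identical(classify_geometry(c(90, 9, 0.9)), "indeterminate")
  # boundary: ratios exactly at the threshold count as dominant
  expect_identical(classify_geometry(c(6, 3, 1)), "sheet")
  expect_identical(classify_geometry(c(9, 3, 1.5)), "bundle")
  # zero smallest size: infinite dominance
  expect_identical(classify_geometry(c(4, 2, 0)), "sheet")
  expect_identical(classify_geometry(c(0, 0, 0)), "indeterminate")
  expect_error(classify_geometry(c(1, 2, 3)), "descending")
  expect_error(classify_geometry(c(1, 2)), "3 values")
})

test_that("the surface fit recovers a planted quadratic height function", {
  g <- expand.grid(u = seq(-5, 5, 0.5), v = seq(-5, 5, 0.5))
  sl <- lapply(split(g, g$v), function(d) cbind(d$u, d$v, 0.1 * d$u^2))
  t <- tractogram(sl)
  fit <- fit_sheet_surface(t, diag(3), degree = 2)
  expect_equal(unname(fit$coefficients[["I(u^2)"]]), 0.1, tolerance = 1e-8)
  expect_lt(fit$residual_sd, 1e-10)
  expect_error(fit_sheet_surface(t, diag(3), degree = 4), "1, 2 or 3")
})

test_that("sheet_model bundles frame, sizes, fit and classification", {
  vp <- make_variance_phantom(c(25, 9, 1), n = 100, pts = 30, seed = 6)
  sm <- sheet_model(vp$tract)
  expect_s3_class(sm, "sheet_model")
  expect_identical(sm$classification, "sheet")
  td <- tidy(sm)
  expect_equal(nrow(td), 3)
  expect_equal(td$size_mm2, sm$sizes)
  gl <- glance(sm)
  expect_equal(gl$classification, "sheet")
  # sizes along the data-driven PCA axes differ from the planted ones only
  # by the sampling error of the estimated rotation
  expect_equal(gl$size1_mm2, 25, tolerance = 0.05)
  expect_s3_class(autoplot(sm), "ggplot")
  expect_output(print(sm), "sheet_model")
})
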