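test_that("compute_snr matches the analytic value for a pure sinusoid", {
  T <- 128L; k <- 8L
  x <- sin(2 * pi * k * (0:(T - 1)) / T + 0.7)
  snr <- compute_snr(fmri_timeseries(matrix(x, 1), k))
  # |X[k]| = T/2 at the stimulus bin and its conjugate, 0 elsewhere;
  # sd over the T-1 non-DC magnitudes is analytic
  mags <- c(rep(0, T - 3), T / 2, T / 2)   # the T - 1 non-DC magnitudes
  expect_equal(snr$values, (T / 2) / sd(mags), tolerance = 1e-10)
  expect_s3_class(snr, "vertex_scalar_map")
  expect_identical(snr$kind, "snr")
})

test_that("compute_snr is scale-invariant and zero on flat series", {
  T <- 64L; k <- 4L
  x <- 100 + sin(2 * pi * k * (0:(T - 1)) / T)
  a <- compute_snr(fmri_timeseries(matrix(x, 1), k))$values
  b <- compute_snr(fmri_timeseries(matrix(7 * x, 1), k))$values
  expect_equal(a, b)
  flat <- compute_snr(fmri_timeseries(matrix(5, 1, T), k))
  expect_equal(flat$values, 0)
})

test_that("doubling the noise on the same pattern lowers the SNR", {
  T <- 128L; k <- 8L
  set.seed(2)
  eps <- rnorm(T)
  sig <- sin(2 * pi * k * (0:(T - 1)) / T)
  lo <- compute_snr(fmri_timeseries(matrix(sig + 0.2 * eps, 1), k))$values
  hi <- compute_snr(fmri_timeseries(matrix(sig + 0.4 * eps, 1), k))$values
  expect_lt(hi, lo)
})

test_that("excluding the stimulus bin raises SNR of a strong response", {
  T <- 64L; k <- 4L
  set.seed(3)
  x <- 10 * sin(2 * pi * k * (0:(T - 1)) / T) + rnorm(T, sd = 0.5)
  ts <- fmri_timeseries(matrix(x, 1), k)
  expect_gt(compute_snr(ts, exclude_stimulus_bin = TRUE)$values,
            compute_snr(ts)$values)
})

test_that("fmri_timeseries and compute_snr reject unusable inputs", {
  expect_error(fmri_timeseries(matrix(1:8, 1), 4), "4 samples per")
  expect_error(fmri_timeseries(matrix(c(1, NA, 3, 4), 1), 1), "finite")
  expect_error(fmri_timeseries(matrix(1:8, 2), 0), ">= 1")
  ts <- fmri_timeseries(matrix(rnorm(16), 2), 2)
  ts$stimulus_frequency <- 8L
  expect_error(compute_snr(ts), "Nyquist")
})

test_that("reliable_mask is boundary-inclusive at the threshold", {
  snr <- vertex_scalar_map(c(4.999, 5, 5.001, 0, 10), kind = "snr")
  expect_equal(reliable_mask(snr, reliability_params(snr_threshold = 5)),
               c(FALSE, TRUE, TRUE, FALSE, TRUE))
})

test_that("one smoothing pass equals the hand-computed neighbourhood means", {
  mesh <- flat_mesh(step = 10, xr = c(0, 20), yr = c(0, 20))  # 3 x 3 grid
  vals <- as.double(1:9)
  map <- vertex_scalar_map(vals, kind = "eccentricity")
  mask <- rep(TRUE, 9)
  sm <- smooth_vertex_map(map, mesh, mask,
                          reliability_params(smoothing_iterations = 1))
  adj <- vertex_adjacency(mesh)
  expected <- vapply(1:9, function(i) mean(vals[c(i, adj[[i]])]), numeric(1))
  expect_equal(sm$values, expected)
})

test_that("unreliable vertices are excluded and come out unvalued", {
  mesh <- flat_mesh(step = 10, xr = c(0, 20), yr = c(0, 20))
  vals <- as.double(1:9)
  vals[5] <- 1e6                       # poisoned unreliable centre vertex
  mask <- rep(TRUE, 9); mask[5] <- FALSE
  sm <- smooth_vertex_map(vertex_scalar_map(vals, kind = "eccentricity"),
                          mesh, mask,
                          reliability_params(smoothing_iterations = 4))
  expect_true(is.na(sm$values[5]))
  expect_false(sm$valid[5])
  # the poisoned value never leaks into any reliable mean
  expect_true(all(sm$values[-5] < 10))
})

test_that("circular smoothing averages across the 0/360 wrap", {
  mesh <- flat_mesh(step = 10, xr = c(0, 10), yr = c(0, 10))  # 2 x 2 grid
  map <- vertex_scalar_map(c(350, 10, 350, 10), kind = "polar_angle")
  sm <- smooth_vertex_map(map, mesh, rep(TRUE, 4),
                          reliability_params(smoothing_iterations = 1))
  # every 1-ring mean mixes 350 and 10: results stay near 0, never near 180
  d <- pmin(sm$values, 360 - sm$values)
  expect_true(all(d <= 20))
})

test_that("an isolated reliable vertex keeps its value and is reported", {
  mesh <- flat_mesh(step = 10, xr = c(0, 20), yr = c(0, 20))
  mask <- rep(FALSE, 9); mask[1] <- TRUE
  map <- vertex_scalar_map(as.double(1:9), kind = "eccentricity")
  expect_message(
    sm <- smooth_vertex_map(map, mesh, mask,
                            reliability_params(smoothing_iterations = 2)),
    "no reliable neighbours")
  expect_equal(sm$values[1], 1)
})

test_that("smoothing rejects maps or masks not bound to the mesh", {
  mesh <- flat_mesh(step = 10, xr = c(0, 20), yr = c(0, 20))
  map9 <- vertex_scalar_map(as.double(1:9), kind = "eccentricity")
  expect_error(smooth_vertex_map(vertex_scalar_map(1:4, kind = "eccentricity"),
                                 mesh, rep(TRUE, 4)), "not bound")
  expect_error(smooth_vertex_map(map9, mesh, rep(TRUE, 3)), "mask length")
})
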