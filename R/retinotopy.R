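#' Phase-encoded fMRI time series per vertex
#'
#' Holds one time series per surface vertex together with the stimulus
#' frequency of the phase-encoded paradigm (in cycles per run) and the
#' sampling interval.  At least four samples per stimulus cycle are
#' required so the stimulus frequency is resolvable well below Nyquist.
#'
#' @param samples numeric V x T matrix (vertices by time points).
#' @param stimulus_frequency integer >= 1, cycles per run.
#' @param tr sampling interval in seconds.
#' @return an `"fmri_timeseries"` object.
#' @export
fmri_timeseries <- function(samples, stimulus_frequency, tr = 2) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!all(is.finite(samples))) abort("fMRI samples must be finite")
  stimulus_frequency <- as.integer(stimulus_frequency)
  if (stimulus_frequency < 1L) abort("stimulus frequency must be >= 1 cycle per run")
  if (ncol(samples) < 4L * stimulus_frequency) {
    abort("need at least 4 samples per stimulus cycle")
  }
  structure(list(samples = samples, stimulus_frequency = stimulus_frequency, tr = tr),
            class = "fmri_timeseries")
}

#' @export
print.fmri_timeseries <- function(x, ...) {
  cat(sprintf("<fmri_timeseries> %d vertices x %d samples, %d cycles/run, TR %gs\n",
              nrow(x$samples), ncol(x$samples), x$stimulus_frequency, x$tr))
  invisible(x)
}

#' Reliability parameters for retinotopic map conditioning
#'
#' @param snr_threshold unitless SNR threshold; vertices with SNR strictly
#'   below it are treated as unreliable.  Default 5.
#' @param smoothing_iterations number of neighbourhood-averaging passes.
#'   Default 4.
#' @return a list with class `"reliability_params"`.
#' @export
reliability_params <- function(snr_threshold = 5, smoothing_iterations = 4) {
  if (snr_threshold <= 0) abort("snr_threshold must be positive")
  smoothing_iterations <- as.integer(smoothing_iterations)
  if (smoothing_iterations < 0) abort("smoothing_iterations must be >= 0")
  structure(list(snr_threshold = snr_threshold,
                 smoothing_iterations = smoothing_iterations),
            class = "reliability_params")
}

#' Spectral signal-to-noise ratio of a phase-encoded response
#'
#' For each vertex, the discrete Fourier spectrum of the full time series
#' is taken; SNR is the magnitude at the stimulus-frequency bin divided by
#' the standard deviation of the spectrum magnitudes over all non-DC bins
#' (the stimulus bin included by default).  A (numerically) zero
#' denominator yields SNR 0.  The statistic is invariant under global
#' scaling of the time series.
#'
#' @param ts an [fmri_timeseries()].
#' @param exclude_stimulus_bin when `TRUE`, the stimulus bin (and its
#'   conjugate) are left out of the denominator.  Default `FALSE`.
#' @return a [vertex_scalar_map()] of kind `"snr"`.
#' @export
compute_snr <- function(ts, exclude_stimulus_bin = FALSE) {
  stopifnot(inherits(ts, "fmri_timeseries"))
  T <- ncol(ts$samples)
  k <- ts$stimulus_frequency
  if (k >= T / 2) abort("stimulus frequency at or above Nyquist")
  X <- mvfft(t(ts$samples))              # T x V complex spectrum
  mag <- Mod(X)
  num <- mag[k + 1L, ]
  rows <- 2:T                            # all non-DC bins
  if (exclude_stimulus_bin) rows <- setdiff(rows, c(k + 1L, T - k + 1L))
  den <- apply(mag[rows, , drop = FALSE], 2, sd)
  snr <- ifelse(den < 1e-12, 0, num / den)
  vertex_scalar_map(snr, kind = "snr")
}

#' Vertex reliability mask from an SNR map
#'
#' A vertex is reliable when its SNR is at least the threshold; vertices
#' strictly below the threshold are excluded.
#'
#' @param snr a [vertex_scalar_map()] of kind `"snr"`.
#' @param params a [reliability_params()].
#' @return logical vector, one flag per vertex.
#' @export
reliable_mask <- function(snr, params = reliability_params()) {
  stopifnot(inherits(snr, "vertex_scalar_map"), snr$kind == "snr")
  snr$valid & snr$values >= params$snr_threshold
}

#' Iterative neighbourhood smoothing of a vertex map
#'
#' One pass replaces each reliable vertex's value with the (unweighted)
#' mean over itself and its reliable 1-ring neighbours; unreliable
#' vertices contribute to no mean and come out unvalued.  Polar-angle maps
#' use the circular (unit-vector) mean.  The pass is repeated
#' `params$smoothing_iterations` times.  Reliable vertices whose only
#' reliable neighbour is themselves keep their value and are reported.
#'
#' @param map a [vertex_scalar_map()] bound to `mesh`.
#' @param mesh the carrying [surface_mesh()].
#' @param mask logical reliability vector (see [reliable_mask()]).
#' @param params a [reliability_params()].
#' @return a smoothed [vertex_scalar_map()]; unreliable vertices are `NA`
#'   with `valid = FALSE`.
#' @export
smooth_vertex_map <- function(map, mesh, mask, params = reliability_params()) {
  stopifnot(inherits(map, "vertex_scalar_map"), inherits(mesh, "surface_mesh"))
  if (length(map) != n_vertices(mesh)) abort("map is not bound to this mesh")
  if (length(mask) != length(map)) abort("mask length must match the map")
  mask <- mask & map$valid
  adj <- vertex_adjacency(mesh)
  circular <- map$kind == "polar_angle"

  vals <- map$values
  vals[!mask] <- NA_real_
  isolated <- logical(length(vals))
  for (it in seq_len(params$smoothing_iterations)) {
    new <- vals
    for (i in which(mask)) {
      nb <- adj[[i]]
      nb <- nb[mask[nb]]
      if (length(nb) == 0) {
        isolated[i] <- TRUE
        next                      # no reliable neighbours: value unchanged
      }
      x <- c(vals[i], vals[nb])
      if (circular) {
        m <- circular_mean_deg(x)
        # an exactly balanced ring has no mean direction; keep the value
        if (!is.na(m)) new[i] <- m
      } else {
        new[i] <- mean(x)
      }
    }
    vals <- new
  }
  if (any(isolated)) {
    inform(sprintf("%d reliable vertex(es) had no reliable neighbours; values left unchanged",
                   sum(isolated)))
  }
  vertex_scalar_map(vals, kind = map$kind, valid = mask)
}
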