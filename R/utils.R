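# internal geometry / circular-statistics helpers

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to the principal interval [0, 360)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles reduced modulo 360 into `[0, 360)`.
#' @export
wrap_degrees <- function(x) {
  out <- x %% 360
  out[out == 360] <- 0
  out
}

#' Circular mean of angles in degrees
#'
#' Mean direction of the unit vectors `(cos x, sin x)`.  Returns `NA` when
#' the resultant vector is (numerically) zero, i.e. the mean direction is
#' undefined.
#'
#' @param x angles in degrees.
#' @param na.rm drop missing values first.
#' @return mean direction in degrees on `[0, 360)`, or `NA`.
#' @export
circular_mean_deg <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  r <- deg2rad(x)
  s <- mean(sin(r)); c <- mean(cos(r))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  wrap_degrees(rad2deg(atan2(s, c)))
}

# signed smallest angular difference a - b in (-180, 180]
angdiff_deg <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

# angle in degrees between two 3D vectors, clamped against rounding
vec_angle_deg <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  rad2deg(acos(max(-1, min(1, sum(u * v) / (nu * nv)))))
}

# row-wise L2 norms of an n x 3 matrix
row_norms <- function(m) sqrt(rowSums(m^2))

# n x 3 matrix coercion with validation
as_points3 <- function(x, what = "points") {
  m <- as.matrix(x)
  if (is.null(dim(m)) || ncol(m) != 3) {
    abort(sprintf("%s must be an n x 3 matrix of coordinates", what))
  }
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

# orthonormalise columns of a 3x3 matrix (modified Gram-Schmidt)
orthonormalise <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(3L, 3L)))
  q <- matrix(0, 3, 3)
  for (j in 1:3) {
    v <- m[, j]
    if (j > 1) for (k in seq_len(j - 1)) v <- v - sum(v * q[, k]) * q[, k]
    n <- sqrt(sum(v^2))
    if (n < 1e-12) abort("frame columns are linearly dependent")
    q[, j] <- v / n
  }
  q
}

# run expr with a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
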