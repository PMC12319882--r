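#' Streamline and tractogram containers
#'
#' A streamline is an ordered polyline of 3D positions in world millimetres
#' (RAS).  A tractogram is a list of streamlines plus a coordinate-space tag
#' and free-text provenance carried over from the file header.
#'
#' Invariants enforced at construction: every streamline has at least two
#' points, all coordinates are finite, and consecutive points are distinct
#' (every segment has positive length).
#'
#' @param points numeric n x 3 matrix of positions (mm).
#' @return `streamline()` returns a `"streamline"` object (an n x 3 matrix).
#' @examples
#' s <- streamline(cbind(0:3, 0, 0))
#' arc_length(s)
#' @export
streamline <- function(points) {
  m <- as_points3(points, "streamline points")
  validate_streamline(m)
  structure(m, class = c("streamline", "matrix", "array"))
}

validate_streamline <- function(m, index = NULL) {
  where <- if (is.null(index)) "streamline" else sprintf("streamline %d", index)
  if (nrow(m) < 2) abort(sprintf("%s has fewer than 2 points", where))
  if (!all(is.finite(m))) abort(sprintf("%s contains non-finite coordinates", where))
  seg <- row_norms(diff(m))
  if (any(seg == 0)) abort(sprintf("%s has repeated consecutive points", where))
  invisible(m)
}

#' @rdname streamline
#' @param streamlines list of streamlines (or n x 3 matrices).
#' @param space coordinate convention tag; only `"RAS"` (world mm) is used.
#' @param provenance character vector of free-text header metadata.
#' @export
tractogram <- function(streamlines, space = "RAS", provenance = character()) {
  streamlines <- lapply(seq_along(streamlines), function(i) {
    m <- as_points3(streamlines[[i]], sprintf("streamline %d", i))
    validate_streamline(m, i)
    structure(m, class = c("streamline", "matrix", "array"))
  })
  structure(
    list(streamlines = streamlines, space = space, provenance = provenance),
    class = "tractogram"
  )
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' @export
print.tractogram <- function(x, ...) {
  n <- length(x)
  npts <- vapply(x$streamlines, nrow, integer(1))
  cat(sprintf("<tractogram> %d streamline(s), space %s\n", n, x$space))
  if (n > 0) {
    cat(sprintf("  points per streamline: %d-%d (median %g)\n",
                min(npts), max(npts), stats::median(npts)))
  }
  invisible(x)
}

#' Tidy view of a tractogram
#'
#' One row per point, with streamline and point indices, so that tractogram
#' geometry can be piped into dplyr/ggplot2.
#'
#' @param t a [tractogram()].
#' @return tibble with columns `streamline`, `point`, `x`, `y`, `z`.
#' @export
tract_points <- function(t) {
  stopifnot(inherits(t, "tractogram"))
  if (length(t) == 0) {
    return(tibble::tibble(streamline = integer(), point = integer(),
                          x = double(), y = double(), z = double()))
  }
  purrr::map_dfr(seq_along(t$streamlines), function(i) {
    m <- t$streamlines[[i]]
    tibble::tibble(streamline = i, point = seq_len(nrow(m)),
                   x = m[, 1], y = m[, 2], z = m[, 3])
  })
}

# pooled points of all streamlines as one matrix
pooled_points <- function(t) {
  do.call(rbind, lapply(t$streamlines, unclass))
}

# keep a subset of streamlines, preserving metadata
subset_tractogram <- function(t, keep) {
  tractogram(t$streamlines[keep], space = t$space, provenance = t$provenance)
}

# ---- TCK container -------------------------------------------------------
# MRtrix track file: a text header terminated by "END\n", then little-endian
# float32 triplets at the byte offset announced by the "file: . <offset>"
# field.  Streamlines are separated by a (NaN,NaN,NaN) triplet and the
# stream is terminated by (Inf,Inf,Inf).

#' Read / write tractograms in TCK format
#'
#' `read_tractogram()` parses an MRtrix TCK file into a [tractogram()]; all
#' header fields are preserved in `provenance`.  `write_tractogram()` writes
#' a TCK file readable by standard streamline tools (Float32LE datatype).
#'
#' @param path file path.
#' @return `read_tractogram()` returns a [tractogram()];
#'   `write_tractogram()` returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".tck")
#' t <- tractogram(list(cbind(c(0, 3), 0, 0)))
#' write_tractogram(t, tf)
#' read_tractogram(tf)
#' @export
read_tractogram <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))

  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!identical(trimws(magic), "mrtrix tracks")) {
    abort(sprintf("not a TCK file (bad magic line): %s", path))
  }
  header <- character()
  offset <- NA_real_
  datatype <- "Float32LE"
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0) abort("malformed TCK header: no END line")
    if (identical(trimws(line), "END")) break
    header <- c(header, line)
    kv <- strsplit(line, ":", fixed = TRUE)[[1]]
    if (length(kv) >= 2) {
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = ":"))
      if (key == "file") {
        parts <- strsplit(val, "[[:space:]]+")[[1]]
        offset <- suppressWarnings(as.numeric(parts[length(parts)]))
      }
      if (key == "datatype") datatype <- val
    }
  }
  if (!is.finite(offset)) abort("malformed TCK header: missing 'file: . <offset>' field")
  if (!datatype %in% c("Float32LE", "Float32BE")) {
    abort(sprintf("unsupported TCK datatype: %s", datatype))
  }
  endian <- if (datatype == "Float32LE") "little" else "big"

  seek(con, where = offset, origin = "start")
  nbytes <- file.size(path) - offset
  raw_n <- floor(nbytes / 4)
  vals <- readBin(con, what = "numeric", n = raw_n, size = 4L, endian = endian)
  if (length(vals) %% 3 != 0) abort("malformed TCK data: byte count is not a multiple of 12")
  m <- matrix(vals, ncol = 3, byrow = TRUE)

  is_sep <- rowSums(is.na(m)) > 0
  is_end <- rowSums(is.infinite(m)) > 0
  end_at <- which(is_end)
  if (length(end_at) > 0) {
    m <- m[seq_len(end_at[1] - 1), , drop = FALSE]
    is_sep <- is_sep[seq_len(end_at[1] - 1)]
  }
  if (nrow(m) == 0) return(tractogram(list(), space = "RAS", provenance = header))
  # an empty record (leading or doubled separator) violates the >= 2 point rule
  if (is_sep[1] || any(is_sep[-1] & is_sep[-length(is_sep)])) {
    abort(sprintf("empty streamline record in %s", path))
  }
  grp <- cumsum(c(TRUE, is_sep[-length(is_sep)])) # streamline id per row
  streamlines <- list()
  idx <- 0L
  for (g in unique(grp[!is_sep])) {
    idx <- idx + 1L
    pts <- m[grp == g & !is_sep, , drop = FALSE]
    if (nrow(pts) < 2) abort(sprintf("streamline %d in %s has fewer than 2 points", idx, path))
    if (!all(is.finite(pts))) abort(sprintf("streamline %d in %s has non-finite coordinates", idx, path))
    streamlines[[idx]] <- pts
  }
  tractogram(streamlines, space = "RAS", provenance = header)
}

#' @rdname read_tractogram
#' @param t a [tractogram()].
#' @export
write_tractogram <- function(t, path) {
  stopifnot(inherits(t, "tractogram"))
  for (i in seq_along(t$streamlines)) validate_streamline(t$streamlines[[i]], i)

  fields <- c(
    sprintf("count: %d", length(t)),
    "datatype: Float32LE",
    grep("^(count|datatype|file):", t$provenance, invert = TRUE, value = TRUE)
  )
  # the offset line length depends on the offset itself; fix by iteration
  make_header <- function(off) {
    paste0(paste(c("mrtrix tracks", fields, sprintf("file: . %d", off), "END"),
                 collapse = "\n"), "\n")
  }
  off <- nchar(make_header(0), type = "bytes")
  while (nchar(make_header(off), type = "bytes") != off) {
    off <- nchar(make_header(off), type = "bytes")
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(make_header(off), con, eos = NULL)
  sep <- c(NaN, NaN, NaN)
  dat <- unlist(lapply(t$streamlines, function(m) c(t(unclass(m)), sep)),
                use.names = FALSE)
  dat <- c(dat, c(Inf, Inf, Inf))
  writeBin(dat, con, size = 4L, endian = "little")
  invisible(path)
}
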