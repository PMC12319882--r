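#' Write a per-streamline or summary report as TSV
#'
#' Tab-separated, one row per record with a column header; rows are
#' ordered deterministically by the `streamline` column when present.
#' Values round-trip through [read_report()] to full double precision.
#'
#' @param records a non-empty data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path) {
  df <- tibble::as_tibble(records)
  if (ncol(df) == 0) abort("records must have at least one column")
  if ("streamline" %in% names(df)) df <- dplyr::arrange(df, .data$streamline)
  df <- df[!vapply(df, is.list, logical(1))]
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
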