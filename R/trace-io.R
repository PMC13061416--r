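#' Write a trace or metrics table as CSV
#'
#' Plain-CSV serialisation for behavior traces, score series, centroid
#' tracks and per-animal metrics tables. Integer and state columns round
#' trip exactly; floating-point columns to better than 1e-9 (written with
#' full precision).
#'
#' @param x A data frame (e.g. a [behavior_trace], a scored trace with
#'   `score`/`x_mm`/`y_mm` columns, or a metrics table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  readr::write_csv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Read a trace/metrics CSV written by [write_trace_csv()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("'%s' does not exist.", path),
          class = "larvasleep_not_found")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
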