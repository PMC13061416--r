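#' Partition an arena frame into a well grid
#'
#' The larval arena is a fixed 24-well (4 x 6) silicone chamber; by default
#' the frame is partitioned into `rows x cols` equal boxes. When the well
#' rims are visible as dark ridges, `refine = TRUE` snaps each internal grid
#' line to the nearest intensity minimum of the row/column mean profile
#' within `search_px`.
#'
#' @param frame A single `H x W` matrix (e.g. `stack[, , 1]`) or a
#'   [frame_stack] (its first frame is used).
#' @param rows,cols Grid dimensions (default 4 x 6 = 24 wells).
#' @param refine Snap grid lines to intensity minima (rim detection).
#' @param search_px Half-width of the rim search window, px.
#' @return A tibble of class `well_grid` with one row per well:
#'   `well_id`, `row`, `col`, and the half-open 0-based pixel bounding box
#'   `top`, `bottom`, `left`, `right`.
#' @export
detect_wells <- function(frame, rows = 4L, cols = 6L, refine = FALSE,
                         search_px = 8L) {
  if (inherits(frame, "frame_stack")) frame <- unclass(frame)[, , 1]
  H <- nrow(frame); W <- ncol(frame)
  assert_scalar_num(rows, "rows", min = 1)
  assert_scalar_num(cols, "cols", min = 1)
  if (rows > H || cols > W) {
    abort("Grid larger than the frame.",
          class = "larvasleep_invalid_parameter")
  }
  row_cuts <- round(seq(0, H, length.out = rows + 1))
  col_cuts <- round(seq(0, W, length.out = cols + 1))
  if (refine) {
    row_cuts <- snap_cuts(row_cuts, rowMeans(frame), search_px)
    col_cuts <- snap_cuts(col_cuts, colMeans(frame), search_px)
  }
  grid <- tidyr::expand_grid(row = seq_len(rows) - 1L,
                             col = seq_len(cols) - 1L)
  out <- grid |>
    mutate(top = row_cuts[.data$row + 1L],
           bottom = row_cuts[.data$row + 2L],
           left = col_cuts[.data$col + 1L],
           right = col_cuts[.data$col + 2L],
           well_id = sprintf("w%02d", row_number())) |>
    select("well_id", "row", "col", "top", "bottom", "left", "right")
  structure(out, class = c("well_grid", class(out)))
}

# Snap internal cut positions to the darkest profile position nearby
# (well rims image as intensity minima). Endpoints stay fixed.
snap_cuts <- function(cuts, profile, search_px) {
  n <- length(profile)
  for (i in seq_along(cuts)[-c(1, length(cuts))]) {
    lo <- max(1L, cuts[i] - search_px + 1L)
    hi <- min(n, cuts[i] + search_px + 1L)
    win <- profile[lo:hi]
    cuts[i] <- lo + which.min(win) - 1L - 1L  # back to 0-based coordinate
  }
  # keep cuts strictly increasing
  cuts <- pmax(cuts, seq_along(cuts) - 1)
  sort(cuts)
}

crop_well <- function(stack, well) {
  arr <- unclass(stack)
  d <- dim(arr)
  if (well$bottom > d[1] || well$right > d[2] || well$top < 0 ||
      well$left < 0) {
    abort("Well box lies outside the frame.",
          class = "larvasleep_invalid_parameter")
  }
  arr[(well$top + 1):well$bottom, (well$left + 1):well$right, , drop = FALSE]
}
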