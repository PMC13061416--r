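#' Frame-differencing pixel-change scores
#'
#' The activity statistic: for each frame t >= 1, the number of in-well
#' pixels whose absolute intensity difference from frame t-1 exceeds
#' `noise_floor`. Counting changed pixels (rather than summing absolute
#' differences) is robust to static illumination gradients. Frame 0 has no
#' predecessor and copies frame 1's score, so recordings never start with a
#' spurious state.
#'
#' @param stack A [frame_stack] with at least 2 frames.
#' @param well Optional single row of a [detect_wells()] grid restricting
#'   scoring to one well; `NULL` scores the whole frame.
#' @param noise_floor Per-pixel absolute intensity change (8-bit units)
#'   below which a pixel is considered unchanged.
#' @return A tibble of class `activity_scores` with columns `frame` and
#'   `score`, and attributes `fps`, `well_id`.
#' @export
pixel_change_scores <- function(stack, well = NULL, noise_floor = 10) {
  assert_scalar_num(noise_floor, "noise_floor", min = 0)
  arr <- if (is.null(well)) unclass(stack) else crop_well(stack, well)
  T_ <- dim(arr)[3]
  if (T_ < 2L) {
    abort("Scoring requires at least 2 frames.",
          class = "larvasleep_invalid_parameter")
  }
  d <- abs(arr[, , -1, drop = FALSE] - arr[, , -T_, drop = FALSE])
  sc <- colSums(matrix(d > noise_floor, ncol = T_ - 1L))
  sc <- c(sc[1], sc)
  out <- tibble(frame = seq_len(T_) - 1L, score = as.numeric(sc))
  structure(out, fps = attr(stack, "fps"),
            well_id = if (is.null(well)) NA_character_ else well$well_id,
            class = c("activity_scores", class(out)))
}

#' Calibrate the active/inactive score threshold
#'
#' Unlabeled mode splits the score histogram into two classes by Otsu's
#' criterion — appropriate when wells contain a mix of quiescent and moving
#' frames. Labeled mode returns the threshold maximising frame-level
#' accuracy against supplied truth labels (scanning the midpoints between
#' adjacent distinct scores, plus one candidate below the minimum). Both
#' modes are deterministic for fixed input; ties resolve to the lowest
#' candidate.
#'
#' @param scores An `activity_scores` tibble (or bare numeric vector).
#' @param labels Optional per-frame truth labels (`"active"`/`"inactive"`),
#'   same length as the scores; both classes must be present.
#' @return A single numeric threshold (classify as active when
#'   `score > threshold`, strictly).
#' @export
calibrate_activity_threshold <- function(scores, labels = NULL) {
  s <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  if (length(s) < 100L) {
    abort("Calibration needs at least 100 frames.",
          class = "larvasleep_invalid_parameter")
  }
  if (is.null(labels)) {
    return(otsu_threshold(s))
  }
  if (length(labels) != length(s)) {
    abort("`labels` must match the scores in length.",
          class = "larvasleep_invalid_parameter")
  }
  if (length(unique(labels)) < 2L) {
    abort("Labeled calibration needs both classes present.",
          class = "larvasleep_invalid_parameter")
  }
  ux <- sort(unique(s))
  cand <- c(ux[1] - 1, (ux[-length(ux)] + ux[-1]) / 2)
  truth_active <- labels == "active"
  acc <- vapply(cand, function(th) mean((s > th) == truth_active),
                numeric(1))
  cand[which.max(acc)]   # which.max -> first (lowest) maximiser
}

#' Classify per-frame activity from pixel-change scores
#'
#' A frame is active iff its score strictly exceeds the threshold; a score
#' equal to the threshold is inactive (conservative toward quiescence). No
#' temporal smoothing is applied by default — the downstream >= 12-frame
#' bout criterion already suppresses single-frame flicker — but a 3-frame
#' median filter on the labels is available behind `median3`.
#'
#' @param scores An `activity_scores` tibble.
#' @param threshold Score cutoff (>= 0), e.g. from
#'   [calibrate_activity_threshold()].
#' @param median3 Apply a 3-frame median filter to the binary labels.
#' @return A [behavior_trace].
#' @export
classify_activity <- function(scores, threshold, median3 = FALSE) {
  assert_scalar_num(threshold, "threshold", min = 0)
  act <- scores$score > threshold
  if (median3 && length(act) >= 3L) {
    act <- as.logical(round(stats::runmed(as.numeric(act), 3L)))
  }
  behavior_trace(ifelse(act, "active", "inactive"),
                 fps = attr(scores, "fps") %||% 0.87,
                 well_id = attr(scores, "well_id") %||% NA_character_)
}

#' Track the larval centroid within a well
#'
#' Background model: per-pixel temporal median over a sliding 101-frame
#' window (the animal moves enough during wake for the median to approach
#' the empty-well background), reinforced per frame by a spatial estimate —
#' the per-column median, which tracks left-right illumination gradients
#' and stays bright where a long-quiescent animal would otherwise be
#' absorbed into the temporal median. The effective background is the
#' pixelwise maximum of the two (the substrate is always the bright
#' component). Foreground is any pixel whose darkening relative to this
#' background exceeds `noise_floor`; the per-frame position is the
#' intensity-weighted centroid of that foreground. Frames with no
#' foreground are flagged invalid and carry the last valid position
#' forward.
#'
#' @param stack A [frame_stack].
#' @param well Optional well-grid row to crop to.
#' @param noise_floor Minimum darkening (8-bit units) counted as
#'   foreground.
#' @param window Sliding median window in frames (odd; shrunk to fit short
#'   recordings).
#' @return A tibble of class `centroid_track` with `frame`, `x_mm`, `y_mm`
#'   (or `x_px`, `y_px` when uncalibrated — see the `units` attribute) and
#'   `valid`.
#' @export
track_centroids <- function(stack, well = NULL, noise_floor = 10,
                            window = 101L) {
  arr <- if (is.null(well)) unclass(stack) else crop_well(stack, well)
  d <- dim(arr)
  H <- d[1]; W <- d[2]; T_ <- d[3]
  k <- min(window, if (T_ %% 2L == 1L) T_ else T_ - 1L)
  if (k < 3L) {
    bg <- matrix(apply(matrix(arr, H * W, T_), 1, median), H, W)
    bg <- array(rep(bg, T_), dim = d)
  } else {
    px <- matrix(arr, H * W, T_)
    bg <- apply(px, 1, stats::runmed, k = k, endrule = "keep")  # T x HW
    # constant extension at the ends (endrule = "keep" leaves raw values)
    half <- (k - 1L) %/% 2L
    bg[seq_len(half), ] <- rep(bg[half + 1L, ], each = half)
    bg[(T_ - half + 1L):T_, ] <- rep(bg[T_ - half, ], each = half)
    bg <- array(t(bg), dim = d)
  }
  col_idx <- matrix(rep(0:(W - 1), each = H), H, W)
  row_idx <- matrix(rep(0:(H - 1), W), H, W)
  xs <- numeric(T_); ys <- numeric(T_); valid <- logical(T_)
  for (t in seq_len(T_)) {
    fr <- arr[, , t]
    spatial_bg <- matrix(apply(fr, 2, median), H, W, byrow = TRUE)
    w <- pmax(bg[, , t], spatial_bg) - fr
    w[w < noise_floor] <- 0
    tot <- sum(w)
    if (tot > 0) {
      xs[t] <- sum(w * col_idx) / tot
      ys[t] <- sum(w * row_idx) / tot
      valid[t] <- TRUE
    }
  }
  if (!any(valid)) {
    abort("No foreground found in any frame; the well appears empty.",
          class = "larvasleep_empty_well")
  }
  first_valid <- which(valid)[1]
  for (t in seq_len(T_)) {
    if (!valid[t]) {
      src <- if (t > first_valid) max(which(valid[seq_len(t)])) else first_valid
      xs[t] <- xs[src]; ys[t] <- ys[src]
    }
  }
  px_mm <- attr(stack, "pixel_size_mm")
  calibrated <- !is.null(px_mm) && !is.na(px_mm)
  scale <- if (calibrated) px_mm else 1
  off_x <- if (is.null(well)) 0 else well$left
  off_y <- if (is.null(well)) 0 else well$top
  out <- tibble(frame = seq_len(T_) - 1L,
                x_mm = (xs + off_x) * scale,
                y_mm = (ys + off_y) * scale,
                valid = valid)
  if (!calibrated) names(out)[2:3] <- c("x_px", "y_px")
  structure(out, units = if (calibrated) "mm" else "px",
            pixel_size_mm = px_mm,
            class = c("centroid_track", class(out)))
}
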