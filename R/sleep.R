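#' Call sleep bouts from a behavior trace
#'
#' Sleep is defined as an inactive state lasting at least `min_frames`
#' consecutive frames (default 12, i.e. ~13.8 s at 0.87 fps). The bouts
#' returned are exactly the maximal inactive runs meeting the criterion,
#' as 0-based half-open frame intervals; runs truncated by the recording
#' edges count if they meet the threshold.
#'
#' @param trace A [behavior_trace].
#' @param min_frames Minimum inactive run length scored as sleep (frames).
#' @return A tibble of class `sleep_bouts` with `start_frame`, `end_frame`
#'   (half-open) and `duration_s`.
#' @examples
#' tr <- behavior_trace(rep(c("active", "inactive", "active"),
#'                          times = c(5, 12, 5)))
#' call_sleep_bouts(tr)
#' @export
call_sleep_bouts <- function(trace, min_frames = 12L) {
  assert_scalar_num(min_frames, "min_frames", min = 1)
  fps <- trace_fps(trace)
  bouts <- runs_of(trace$state, "inactive") |>
    filter(.data$end_frame - .data$start_frame >= min_frames) |>
    mutate(duration_s = (.data$end_frame - .data$start_frame) / fps)
  structure(bouts, fps = fps, min_frames = as.integer(min_frames),
            well_id = attr(trace, "well_id"),
            class = c("sleep_bouts", class(bouts)))
}

#' Sleep architecture metrics over an analysis window
#'
#' Total sleep is the summed overlap of the sleep bouts with the window;
#' wake is its exact complement, so `total_sleep_s + total_wake_s` equals
#' the window length. Latency is the start (relative to the window) of the
#' first bout intersecting it, `NA` when no bout does.
#'
#' @param trace A [behavior_trace].
#' @param bouts Bouts from [call_sleep_bouts()] on this trace; computed if
#'   omitted.
#' @param window `c(start_s, end_s)` within the recording; defaults to the
#'   whole recording.
#' @param min_frames Passed to [call_sleep_bouts()] when `bouts` is NULL.
#' @return A one-row tibble: `window_start_s`, `window_end_s`,
#'   `total_sleep_s`, `total_wake_s`, `bout_count`, `mean_bout_s`,
#'   `sleep_latency_s`, `sleep_fraction`.
#' @export
sleep_metrics <- function(trace, bouts = NULL, window = NULL,
                          min_frames = 12L) {
  fps <- trace_fps(trace)
  rec_len <- nrow(trace) / fps
  if (is.null(window)) window <- c(0, rec_len)
  if (window[1] < 0 || window[2] > rec_len + 1e-9 ||
      window[2] <= window[1]) {
    abort("`window` must be a non-empty interval within the recording.",
          class = "larvasleep_invalid_parameter")
  }
  if (is.null(bouts)) bouts <- call_sleep_bouts(trace, min_frames)
  b_start <- bouts$start_frame / fps
  b_end <- bouts$end_frame / fps
  ovl <- pmax(0, pmin(b_end, window[2]) - pmax(b_start, window[1]))
  total_sleep <- sum(ovl)
  hit <- ovl > 0
  latency <- if (any(hit)) max(0, b_start[hit][1] - window[1]) else NA_real_
  tibble(window_start_s = window[1], window_end_s = window[2],
         total_sleep_s = total_sleep,
         total_wake_s = (window[2] - window[1]) - total_sleep,
         bout_count = sum(hit),
         mean_bout_s = if (any(hit)) mean(ovl[hit]) else NA_real_,
         sleep_latency_s = latency,
         sleep_fraction = total_sleep / (window[2] - window[1]))
}

#' Wake-gated locomotion speed
#'
#' Locomotion speed is total centroid travel distance divided by total
#' wake duration, considering only time classified as wake: each
#' inter-frame displacement is attributed to its destination frame and
#' counted only when that frame is wake and both endpoints were validly
#' tracked; the matching time is removed from the denominator otherwise.
#' Excluding sleep from both terms makes the speed invariant to the
#' fraction of time spent asleep.
#'
#' @param track A `centroid_track` from [track_centroids()].
#' @param bouts Sleep bouts from [call_sleep_bouts()] (frames inside them
#'   are sleep); an empty/NULL bout set treats every frame as wake.
#' @param fps Frame rate; defaults to the bout attribute.
#' @return A one-row tibble: `distance_mm`, `wake_time_s`, `speed_mm_s`
#'   (`NA` with a warning when there is no validly tracked wake time).
#'   Columns are in px units when the track is uncalibrated.
#' @export
locomotion_speed <- function(track, bouts = NULL, fps = NULL) {
  fps <- fps %||% attr(bouts, "fps") %||% 0.87
  T_ <- nrow(track)
  coords <- as.matrix(track[, intersect(c("x_mm", "y_mm", "x_px", "y_px"),
                                        names(track))])
  sleep <- rep(FALSE, T_)
  if (!is.null(bouts)) {
    for (i in seq_len(nrow(bouts))) {
      sleep[(bouts$start_frame[i] + 1):bouts$end_frame[i]] <- TRUE
    }
  }
  if (T_ < 2L) {
    warn("Track too short for a speed estimate.")
    return(tibble(distance_mm = 0, wake_time_s = 0, speed_mm_s = NA_real_))
  }
  t <- 2:T_
  use <- !sleep[t] & track$valid[t] & track$valid[t - 1L]
  steps <- sqrt(rowSums((coords[t, , drop = FALSE] -
                           coords[t - 1L, , drop = FALSE])^2))
  dist <- sum(steps[use])
  wake_time <- sum(use) / fps
  if (wake_time == 0) {
    warn("No validly tracked wake time; speed is undefined.")
    return(tibble(distance_mm = dist, wake_time_s = 0,
                  speed_mm_s = NA_real_))
  }
  tibble(distance_mm = dist, wake_time_s = wake_time,
         speed_mm_s = dist / wake_time)
}

#' Optogenetic light-response index
#'
#' Sleep during the 1 hr light-ON period normalised to sleep during the
#' 1 hr light-OFF baseline.
#'
#' @param sleep_on_s,sleep_off_s Sleep durations (s) in the ON and OFF
#'   phases; both must be non-negative.
#' @return `sleep_on_s / sleep_off_s`, or `NA` with a warning when the
#'   baseline is zero.
#' @export
light_response_index <- function(sleep_on_s, sleep_off_s) {
  assert_scalar_num(sleep_on_s, "sleep_on_s", min = 0)
  assert_scalar_num(sleep_off_s, "sleep_off_s", min = 0)
  if (sleep_off_s == 0) {
    warn("Zero light-OFF sleep; light-response index is undefined.")
    return(NA_real_)
  }
  sleep_on_s / sleep_off_s
}

#' Rebound index after sleep deprivation
#'
#' Post-deprivation sleep relative to the matched pre-deprivation
#' baseline; values above 1 indicate a homeostatic rebound.
#'
#' @param sleep_pre_s,sleep_post_s Sleep durations (s) before and after
#'   deprivation.
#' @return `sleep_post_s / sleep_pre_s`, or `NA` with a warning when the
#'   baseline is zero.
#' @export
rebound_index <- function(sleep_pre_s, sleep_post_s) {
  assert_scalar_num(sleep_pre_s, "sleep_pre_s", min = 0)
  assert_scalar_num(sleep_post_s, "sleep_post_s", min = 0)
  if (sleep_pre_s == 0) {
    warn("Zero baseline sleep; rebound index is undefined.")
    return(NA_real_)
  }
  sleep_post_s / sleep_pre_s
}

#' Sleep-deprivation stimulus schedule
#'
#' The deprivation protocol records a baseline hour without stimulation,
#' then a session of repeated cycles of LED ON for `on_s` and OFF for
#' `off_s` (defaults 90 s ON / 30 s OFF for one hour). ON intervals begin
#' at `baseline_s` and repeat with period `on_s + off_s`; a final partial
#' ON interval is truncated at the session end.
#'
#' @param baseline_s Unstimulated baseline duration, s.
#' @param on_s,off_s Stimulus ON and OFF durations per cycle, s.
#' @param session_s Stimulation session duration, s.
#' @return A tibble of class `stimulus_schedule` with half-open second
#'   intervals `on_start_s`, `on_end_s`; parameters are kept as
#'   attributes.
#' @examples
#' sched <- deprivation_schedule()
#' nrow(sched)                       # 30 cycles
#' sum(sched$on_end_s - sched$on_start_s)   # 2700 s of stimulation
#' @export
deprivation_schedule <- function(baseline_s = 3600, on_s = 90, off_s = 30,
                                 session_s = 3600) {
  assert_scalar_num(baseline_s, "baseline_s", min = 0)
  assert_scalar_num(on_s, "on_s", min = 0)
  assert_scalar_num(off_s, "off_s", min = 0)
  assert_scalar_num(session_s, "session_s", min = 0)
  if (on_s + off_s == 0 && session_s > 0) {
    abort("on_s + off_s must be positive for a non-empty session.",
          class = "larvasleep_invalid_parameter")
  }
  session_end <- baseline_s + session_s
  starts <- if (session_s > 0 && on_s > 0) {
    n_cycles <- ceiling(session_s / (on_s + off_s))
    baseline_s + (seq_len(n_cycles) - 1) * (on_s + off_s)
  } else {
    numeric(0)
  }
  out <- tibble(on_start_s = starts,
                on_end_s = pmin(starts + on_s, session_end))
  structure(out, baseline_s = baseline_s, on_s = on_s, off_s = off_s,
            session_s = session_s,
            class = c("stimulus_schedule", class(out)))
}
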