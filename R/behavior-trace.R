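#' Construct a behavior trace
#'
#' A behavior trace is the substrate of all larval sleep metrics: one row per
#' video frame, each labelled `"active"` or `"inactive"`. The frame rate is
#' carried as an attribute so downstream metrics can convert frame counts to
#' seconds.
#'
#' @param states Character vector of per-frame labels, each `"active"` or
#'   `"inactive"`.
#' @param fps Frame rate in frames per second (default 0.87, the acquisition
#'   rate of the larval arena recordings this pipeline targets).
#' @param well_id Optional identifier of the source well/animal.
#'
#' @return A tibble of class `behavior_trace` with columns `frame` (0-based)
#'   and `state`, and attributes `fps` and `well_id`.
#' @export
behavior_trace <- function(states, fps = 0.87, well_id = NA_character_) {
  assert_scalar_num(fps, "fps", min = 0, strict_min = TRUE)
  if (length(states) > 0 && !all(states %in% c("active", "inactive"))) {
    abort("`states` must only contain \"active\" or \"inactive\".",
          class = "larvasleep_invalid_parameter")
  }
  out <- tibble(frame = seq_along(states) - 1L, state = as.character(states))
  structure(out,
            fps = fps, well_id = well_id,
            class = c("behavior_trace", class(out)))
}

#' @export
print.behavior_trace <- function(x, ...) {
  cat(sprintf("<behavior_trace> %d frames @ %.3g fps (%.1f s)\n",
              nrow(x), attr(x, "fps"), nrow(x) / attr(x, "fps")))
  NextMethod()
}

trace_fps <- function(trace) {
  fps <- attr(trace, "fps")
  if (is.null(fps)) {
    abort("Trace has no `fps` attribute; construct it with behavior_trace().",
          class = "larvasleep_invalid_parameter")
  }
  fps
}

#' Ground truth attached to a simulated object
#'
#' Simulated traces, videos and images carry the generating truth (states,
#' bouts, centroid path, nuclear fraction, ...) as an attribute; this
#' accessor returns it.
#'
#' @param x A simulated object produced by one of the `simulate_*()` or
#'   `render_*()` generators.
#' @return A list of ground-truth components, or `NULL` if none is attached.
#' @export
ground_truth <- function(x) attr(x, "ground_truth", exact = TRUE)

#' Simulate an alternating wake/sleep behavior trace
#'
#' Generates a per-frame active/inactive sequence as alternating wake and
#' sleep bouts whose lengths (in frames) are geometrically distributed with
#' the requested mean durations. The geometric law is memoryless — the
#' simplest bout-duration model with a free mean — which makes analytic
#' checks of bout statistics straightforward.
#'
#' A zero `mean_sleep_s` yields an all-active trace; a zero `mean_wake_s` an
#' all-inactive one. The first bout's type is drawn with probability
#' proportional to the two mean durations, so long traces approach the
#' stationary wake/sleep time fractions.
#'
#' @param fps Frame rate, frames/s.
#' @param duration_s Total recording duration in seconds.
#' @param mean_wake_s,mean_sleep_s Mean wake and sleep bout durations in
#'   seconds. Both must be non-negative and not both zero.
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   traces.
#'
#' @return A [behavior_trace] whose `ground_truth()` holds `state_sequence`,
#'   `true_bouts` (maximal inactive runs as 0-based half-open frame
#'   intervals), and the generating parameters.
#' @examples
#' tr <- simulate_behavior_trace(duration_s = 600, mean_wake_s = 90,
#'                               mean_sleep_s = 60, seed = 1)
#' table(tr$state)
#' @export
simulate_behavior_trace <- function(fps = 0.87, duration_s,
                                    mean_wake_s = 90, mean_sleep_s = 60,
                                    seed = 0L) {
  assert_scalar_num(fps, "fps", min = 0, strict_min = TRUE)
  assert_scalar_num(duration_s, "duration_s", min = 0, strict_min = TRUE)
  assert_scalar_num(mean_wake_s, "mean_wake_s", min = 0)
  assert_scalar_num(mean_sleep_s, "mean_sleep_s", min = 0)
  if (mean_wake_s == 0 && mean_sleep_s == 0) {
    abort("mean_wake_s and mean_sleep_s cannot both be zero.",
          class = "larvasleep_invalid_parameter")
  }
  n_frames <- max(1L, as.integer(round(duration_s * fps)))

  states <- with_seed(seed, {
    if (mean_sleep_s == 0) {
      rep("active", n_frames)
    } else if (mean_wake_s == 0) {
      rep("inactive", n_frames)
    } else {
      # geometric on {1, 2, ...} with mean = mean duration in frames
      mw <- max(1, mean_wake_s * fps)
      ms <- max(1, mean_sleep_s * fps)
      first_active <- runif(1) < mean_wake_s / (mean_wake_s + mean_sleep_s)
      out <- character(0)
      active <- first_active
      while (length(out) < n_frames) {
        m <- if (active) mw else ms
        len <- stats::rgeom(1L, prob = 1 / m) + 1L
        out <- c(out, rep(if (active) "active" else "inactive", len))
        active <- !active
      }
      out[seq_len(n_frames)]
    }
  })

  tr <- behavior_trace(states, fps = fps)
  attr(tr, "ground_truth") <- list(
    state_sequence = states,
    true_bouts = runs_of(states, "inactive"),
    seed = as.integer(seed),
    params = list(fps = fps, duration_s = duration_s,
                  mean_wake_s = mean_wake_s, mean_sleep_s = mean_sleep_s)
  )
  tr
}
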