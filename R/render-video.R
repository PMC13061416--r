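#' Motion and imaging parameters for the larva renderer
#'
#' Defaults emulate a second-instar larva in one well of a 24-well arena
#' imaged at 0.87 fps: a dark ~1.5 mm animal crawling at ~0.3 mm/s on a
#' bright substrate, mild peristaltic shape change, additive sensor noise
#' and a static linear illumination gradient.
#'
#' @param fps Frame rate, frames/s.
#' @param crawl_speed_mean Mean centroid speed during wake, mm/s.
#' @param peristalsis_amplitude Amplitude of body-length oscillation, px.
#' @param body_length Larva length, px.
#' @param noise_sd Additive Gaussian sensor noise SD, 8-bit intensity units.
#' @param illum_gradient Fractional left-to-right illumination change.
#' @param pixel_size_mm Optical calibration, mm per pixel.
#' @param turn_sd SD of the per-frame heading change (radians) of the
#'   correlated random walk followed during wake.
#' @param micro_movement_px Optional sub-threshold centroid jitter during
#'   sleep (px, uniform); 0 disables it. Useful to stress thresholding.
#' @return A list of class `motion_params`.
#' @export
motion_params <- function(fps = 0.87, crawl_speed_mean = 0.3,
                          peristalsis_amplitude = 2, body_length = 15,
                          noise_sd = 2, illum_gradient = 0.1,
                          pixel_size_mm = 0.1, turn_sd = 0.5,
                          micro_movement_px = 0) {
  assert_scalar_num(fps, "fps", min = 0, strict_min = TRUE)
  assert_scalar_num(crawl_speed_mean, "crawl_speed_mean", min = 0)
  assert_scalar_num(noise_sd, "noise_sd", min = 0)
  assert_scalar_num(pixel_size_mm, "pixel_size_mm", min = 0,
                    strict_min = TRUE)
  structure(list(fps = fps, crawl_speed_mean = crawl_speed_mean,
                 peristalsis_amplitude = peristalsis_amplitude,
                 body_length = body_length, noise_sd = noise_sd,
                 illum_gradient = illum_gradient,
                 pixel_size_mm = pixel_size_mm, turn_sd = turn_sd,
                 micro_movement_px = micro_movement_px),
            class = "motion_params")
}

#' Render a single-well larva video from a behavior trace
#'
#' Draws the larva as a dark ellipse on a bright substrate. During active
#' frames the centroid advances along a correlated random walk at the
#' programmed crawl speed and the body length oscillates sinusoidally (a
#' peristalsis proxy); during inactive frames the animal is frozen and only
#' sensor noise varies. The true per-frame centroid path is recorded in the
#' returned stack's ground truth, with centroids exactly constant within
#' inactive runs.
#'
#' Steps that would leave the well are reflected off the wall, preserving
#' step length, so the mean per-wake-frame displacement matches
#' `crawl_speed_mean / fps`.
#'
#' @param trace A [behavior_trace] (typically from
#'   [simulate_behavior_trace()]).
#' @param motion A [motion_params] list.
#' @param well_size_px `c(height, width)` of the well image in px.
#' @param seed Integer seed for path and noise randomness.
#' @return A [frame_stack] whose `ground_truth()` holds a tibble
#'   (`frame`, `state`, `x_mm`, `y_mm`) plus the generating parameters.
#' @export
render_larva_video <- function(trace, motion = motion_params(),
                               well_size_px = c(100, 100), seed = 0L) {
  H <- well_size_px[1]; W <- well_size_px[2]
  a_max <- motion$body_length / 2 + abs(motion$peristalsis_amplitude)
  margin <- a_max + 2
  if (2 * margin >= min(H, W)) {
    abort("Larva geometry exceeds well bounds; enlarge the well or shrink the larva.",
          class = "larvasleep_invalid_parameter")
  }
  states <- trace$state
  T_ <- length(states)
  fps <- trace_fps(trace)
  step_px <- motion$crawl_speed_mean / fps / motion$pixel_size_mm

  out <- with_seed(seed, {
    # --- centroid path and body pose -----------------------------------
    cx <- numeric(T_); cy <- numeric(T_)   # (col, row) in px, 0-based
    heading <- runif(1, 0, 2 * pi)
    phase <- runif(1, 0, 2 * pi)
    phases <- numeric(T_); headings <- numeric(T_)
    cx[1] <- runif(1, margin, W - 1 - margin)
    cy[1] <- runif(1, margin, H - 1 - margin)
    for (t in seq_len(T_)) {
      if (t > 1L) {
        if (states[t] == "active") {
          heading <- heading + rnorm(1, 0, motion$turn_sd)
          nx <- cx[t - 1] + step_px * cos(heading)
          ny <- cy[t - 1] + step_px * sin(heading)
          # reflect off walls, preserving step length
          lo_x <- margin; hi_x <- W - 1 - margin
          lo_y <- margin; hi_y <- H - 1 - margin
          if (nx < lo_x) nx <- 2 * lo_x - nx
          if (nx > hi_x) nx <- 2 * hi_x - nx
          if (ny < lo_y) ny <- 2 * lo_y - ny
          if (ny > hi_y) ny <- 2 * hi_y - ny
          nx <- min(max(nx, lo_x), hi_x)
          ny <- min(max(ny, lo_y), hi_y)
          heading <- atan2(ny - cy[t - 1], nx - cx[t - 1])
          cx[t] <- nx; cy[t] <- ny
          phase <- phase + pi / 2
        } else {
          cx[t] <- cx[t - 1]; cy[t] <- cy[t - 1]
          if (motion$micro_movement_px > 0) {
            cx[t] <- cx[t] + runif(1, -1, 1) * motion$micro_movement_px
            cy[t] <- cy[t] + runif(1, -1, 1) * motion$micro_movement_px
          }
        }
      }
      phases[t] <- phase; headings[t] <- heading
    }

    # --- rasterise ------------------------------------------------------
    bg_level <- 200; larva_level <- 80
    col_idx <- matrix(rep(0:(W - 1), each = H), H, W)
    row_idx <- matrix(rep(0:(H - 1), W), H, W)
    gradient <- 1 + motion$illum_gradient * (col_idx / max(1, W - 1) - 0.5)
    base <- bg_level * gradient
    frames <- array(0, dim = c(H, W, T_))
    b_ax <- motion$body_length / 4
    for (t in seq_len(T_)) {
      a_ax <- motion$body_length / 2 +
        motion$peristalsis_amplitude * sin(phases[t])
      dx <- col_idx - cx[t]; dy <- row_idx - cy[t]
      u <- dx * cos(headings[t]) + dy * sin(headings[t])
      v <- -dx * sin(headings[t]) + dy * cos(headings[t])
      inside <- (u / a_ax)^2 + (v / b_ax)^2 <= 1
      fr <- base
      fr[inside] <- larva_level * gradient[inside]
      if (motion$noise_sd > 0) {
        fr <- fr + rnorm(H * W, 0, motion$noise_sd)
      }
      frames[, , t] <- clip8(fr)
    }
    list(frames = frames, cx = cx, cy = cy)
  })

  stack <- frame_stack(out$frames, fps = fps,
                       pixel_size_mm = motion$pixel_size_mm)
  attr(stack, "ground_truth") <- list(
    path = tibble(frame = seq_len(T_) - 1L, state = states,
                  x_mm = out$cx * motion$pixel_size_mm,
                  y_mm = out$cy * motion$pixel_size_mm),
    state_sequence = states,
    true_bouts = runs_of(states, "inactive"),
    seed = as.integer(seed),
    motion = motion
  )
  stack
}
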