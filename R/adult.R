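#' Score adult sleep from a DAM series
#'
#' Adult sleep follows the conventional immobility-gap criterion: maximal
#' runs of consecutive 1-min bins with zero beam crossings, of length at
#' least `min_gap_min` (default 5), become sleep bouts. Bins whose status
#' is not valid break zero runs and are never counted as immobility —
#' missing data is not imputed as sleep. Runs truncated by the recording
#' edges count if they meet the threshold.
#'
#' @param series A [dam_series].
#' @param min_gap_min Minimum zero-count run length (minutes).
#' @return A tibble of class `adult_sleep_bouts` with one row per bout:
#'   `channel`, `start_min`, `end_min` (0-based half-open), `duration_min`.
#'   LD-cycle attributes of the input are propagated.
#' @export
score_adult_sleep <- function(series, min_gap_min = 5L) {
  assert_scalar_num(min_gap_min, "min_gap_min", min = 1)
  tb <- as_tibble(series)
  bouts <- tb |>
    group_by(.data$channel) |>
    arrange(.data$minute, .by_group = TRUE) |>
    summarise(bouts = list(zero_runs(.data$minute, .data$count,
                                     .data$status, min_gap_min)),
              .groups = "drop") |>
    tidyr::unnest("bouts")
  structure(bouts,
            start_minute_of_day = attr(series, "start_minute_of_day"),
            lights_on = attr(series, "lights_on"),
            lights_off = attr(series, "lights_off"),
            min_gap_min = as.integer(min_gap_min),
            class = c("adult_sleep_bouts", class(bouts)))
}

zero_runs <- function(minute, count, status, min_gap_min) {
  if (any(diff(minute) != 1L)) {
    abort("DAM bins are not uniformly spaced at 1 min.",
          class = "larvasleep_ordering_error")
  }
  quiet <- count == 0 & status == DAM2_STATUS_VALID
  r <- runs_of(ifelse(quiet, "inactive", "active"), "inactive")
  r <- r[r$end_frame - r$start_frame >= min_gap_min, ]
  tibble(start_min = minute[1] + r$start_frame,
         end_min = minute[1] + r$end_frame,
         duration_min = r$end_frame - r$start_frame)
}

#' Split adult sleep bouts into day and night components
#'
#' Each bout minute is labelled day or night by its clock time under the
#' LD cycle (default lights on 09:00, off 21:00); a bout crossing a
#' transition contributes minutes to both phases.
#'
#' @param bouts An `adult_sleep_bouts` tibble from [score_adult_sleep()].
#' @param lights_on,lights_off Clock times ("HH:MM" or minutes past
#'   midnight).
#' @return A tibble with one row per channel: `day_sleep_min`,
#'   `night_sleep_min`, `total_sleep_min`.
#' @export
ld_phase_split <- function(bouts, lights_on = NULL, lights_off = NULL) {
  lights_on <- parse_clock_min(lights_on %||% attr(bouts, "lights_on") %||%
                                 "09:00")
  lights_off <- parse_clock_min(lights_off %||%
                                  attr(bouts, "lights_off") %||% "21:00")
  if (lights_on == lights_off) {
    abort("lights_on and lights_off must differ.",
          class = "larvasleep_invalid_parameter")
  }
  start_mod <- attr(bouts, "start_minute_of_day") %||% 540L
  is_day <- function(mod) {
    if (lights_on < lights_off) {
      mod >= lights_on & mod < lights_off
    } else {
      mod >= lights_on | mod < lights_off
    }
  }
  per_bout <- map2(bouts$start_min, bouts$end_min, function(s, e) {
    mods <- (start_mod + s:(e - 1L)) %% 1440L
    day <- sum(is_day(mods))
    c(day = day, night = (e - s) - day)
  })
  bouts |>
    as_tibble() |>
    mutate(day_min = map_dbl(per_bout, "day"),
           night_min = map_dbl(per_bout, "night")) |>
    group_by(.data$channel) |>
    summarise(day_sleep_min = sum(.data$day_min),
              night_sleep_min = sum(.data$night_min),
              total_sleep_min = sum(.data$duration_min),
              .groups = "drop")
}

#' Per-day adult sleep summary
#'
#' Summarises scored bouts per channel and 24-h window aligned to the
#' start of the recording (recordings begin at lights-on), with day/night
#' components from [ld_phase_split()].
#'
#' @param bouts An `adult_sleep_bouts` tibble.
#' @param n_days Number of 24-h windows to summarise (default 2, the
#'   standard two successive recording days).
#' @return A tibble: `channel`, `day`, `total_sleep_min`, `day_sleep_min`,
#'   `night_sleep_min`, `bout_count`, `mean_bout_min`.
#' @export
adult_sleep_summary <- function(bouts, n_days = 2L) {
  out <- map(seq_len(n_days) - 1L, function(d) {
    w0 <- d * 1440L; w1 <- w0 + 1440L
    clipped <- bouts |>
      as_tibble() |>
      mutate(start_min = pmax(.data$start_min, w0),
             end_min = pmin(.data$end_min, w1)) |>
      filter(.data$end_min > .data$start_min) |>
      mutate(duration_min = .data$end_min - .data$start_min)
    attributes(clipped) <- c(attributes(clipped),
                             attributes(bouts)[c("start_minute_of_day",
                                                 "lights_on", "lights_off")])
    if (nrow(clipped) == 0) {
      return(tibble(channel = integer(), day = integer(),
                    total_sleep_min = numeric(), day_sleep_min = numeric(),
                    night_sleep_min = numeric(), bout_count = integer(),
                    mean_bout_min = numeric()))
    }
    split <- ld_phase_split(clipped)
    clipped |>
      group_by(.data$channel) |>
      summarise(bout_count = n(),
                mean_bout_min = mean(.data$duration_min),
                .groups = "drop") |>
      left_join(split, by = "channel") |>
      mutate(day = d + 1L) |>
      select("channel", "day", "total_sleep_min", "day_sleep_min",
             "night_sleep_min", "bout_count", "mean_bout_min")
  })
  list_rbind(out)
}
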