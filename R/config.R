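#' Pipeline run configuration
#'
#' Bundles every tunable the pipeline uses, with defaults matching the
#' study design this package implements: 0.87 fps acquisition, sleep
#' defined as >= 12 consecutive inactive frames, the adult criterion of
#' > 5 min without beam-crossing, and a deprivation schedule of 90 s ON /
#' 30 s OFF cycles after a 1 hr baseline.
#'
#' @param fps Larval video frame rate, frames/s.
#' @param min_sleep_frames Minimum inactive run length scored as sleep.
#' @param adult_min_gap_min Minimum zero-count gap (min) scored as adult
#'   sleep.
#' @param deprivation List with `baseline_s`, `on_s`, `off_s`, `session_s`.
#' @param pixel_size_mm Optical calibration, mm/px (`NA` = uncalibrated).
#' @param noise_floor Per-pixel intensity-change floor for the
#'   frame-differencing classifier.
#' @param seed Integer seed used by any stochastic pipeline step.
#' @param comparisons Optional list of declared comparison families for
#'   [run_compare()]: each element a character vector of group labels
#'   making up one Bonferroni family.
#' @return A list of class `run_config`.
#' @export
run_config <- function(fps = 0.87, min_sleep_frames = 12L,
                       adult_min_gap_min = 5L,
                       deprivation = list(baseline_s = 3600, on_s = 90,
                                          off_s = 30, session_s = 3600),
                       pixel_size_mm = 0.1, noise_floor = 10,
                       seed = 0L, comparisons = NULL) {
  assert_scalar_num(fps, "fps", min = 0, strict_min = TRUE)
  assert_scalar_num(min_sleep_frames, "min_sleep_frames", min = 1)
  assert_scalar_num(adult_min_gap_min, "adult_min_gap_min", min = 1)
  structure(list(fps = fps,
                 min_sleep_frames = as.integer(min_sleep_frames),
                 adult_min_gap_min = as.integer(adult_min_gap_min),
                 deprivation = deprivation,
                 pixel_size_mm = pixel_size_mm,
                 noise_floor = noise_floor,
                 seed = as.integer(seed),
                 comparisons = comparisons),
            class = "run_config")
}

#' Read / write a run configuration as flat JSON
#'
#' @param config A [run_config].
#' @param path JSON file path.
#' @return `read_config()` returns a [run_config]; `write_config()` its
#'   path, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("'%s' does not exist.", path),
          class = "larvasleep_not_found")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- run_config()
  for (nm in names(raw)) defaults[[nm]] <- raw[[nm]]
  structure(defaults, class = "run_config")
}
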