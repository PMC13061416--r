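#' Simulate a full ground-truthed artifact bundle
#'
#' Writes, under `out_dir`: one single-well larva video (multi-page TIFF)
#' plus truth CSV per well, a two-day DAM monitor file with its programmed
#' schedule, a two-channel translocation cell image (TIFF pair), a dyed
#' larva photo (PNG), the resolved configuration and a provenance sidecar.
#' Per-well seeds are derived as `config$seed * 1000 + well`, keeping every
#' artifact reproducible from the single configured seed.
#'
#' @param config A [run_config].
#' @param out_dir Output directory (created if needed).
#' @param n_wells Number of wells/animals to simulate.
#' @param duration_s Video duration per well, s.
#' @param mean_wake_s,mean_sleep_s Bout-duration means for the simulated
#'   behavior.
#' @param well_size_px Well image size.
#' @return Invisibly, a tibble manifest of the written artifacts.
#' @export
run_simulate <- function(config = run_config(), out_dir,
                         n_wells = 24L, duration_s = 600,
                         mean_wake_s = 90, mean_sleep_s = 60,
                         well_size_px = c(100, 100)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("Cannot create '%s'.", out_dir),
          class = "larvasleep_io_error")
  }
  motion <- motion_params(fps = config$fps,
                          pixel_size_mm = config$pixel_size_mm)
  files <- list()
  for (w in seq_len(n_wells)) {
    seed_w <- config$seed * 1000L + w
    tr <- simulate_behavior_trace(fps = config$fps, duration_s = duration_s,
                                  mean_wake_s = mean_wake_s,
                                  mean_sleep_s = mean_sleep_s,
                                  seed = seed_w)
    stack <- render_larva_video(tr, motion = motion,
                                well_size_px = well_size_px, seed = seed_w)
    vid <- file.path(out_dir, sprintf("well_%02d.tif", w))
    truth_csv <- file.path(out_dir, sprintf("well_%02d_truth.csv", w))
    write_frame_stack(stack, vid)
    write_trace_csv(ground_truth(stack)$path, truth_csv)
    files[[length(files) + 1L]] <- tibble(kind = "video", path = vid)
    files[[length(files) + 1L]] <- tibble(kind = "truth", path = truth_csv)
  }
  # adult DAM series: asleep during a regular nightly block
  sched <- tibble(start_min = c(780L, 2220L), end_min = c(1380L, 2820L))
  dam <- simulate_dam_series(sched, mean_counts_awake = 5,
                             n_minutes = 2880L, seed = config$seed)
  dam_path <- file.path(out_dir, "monitor01.txt")
  write_dam2(dam, dam_path)
  readr::write_csv(sched, file.path(out_dir, "monitor01_truth.csv"),
                   progress = FALSE)
  files[[length(files) + 1L]] <- tibble(kind = "dam", path = dam_path)
  # translocation cell image + dyed larva
  ci <- render_translocation_image(0.7, seed = config$seed)
  tiff::writeTIFF(ci$reference / max(ci$reference),
                  file.path(out_dir, "cells_reference.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(ci$reporter / max(ci$reporter),
                  file.path(out_dir, "cells_reporter.tif"),
                  bits.per.sample = 16L)
  photo <- render_dyed_larva(0.3, seed = config$seed)
  png::writePNG(unclass(photo) / 255, file.path(out_dir, "larva_dyed.png"))
  files[[length(files) + 1L]] <- tibble(kind = "cells",
                                        path = file.path(out_dir,
                                                         "cells_reporter.tif"))
  write_config(config, file.path(out_dir, "config.json"))
  jsonlite::write_json(
    list(tool = "larvasleep",
         version = as.character(utils::packageVersion("larvasleep")),
         seed = config$seed),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
  invisible(list_rbind(files))
}

#' Score larval sleep and locomotion for every well video in a directory
#'
#' For each `well_*.tif` in `input_dir`: pixel-change scoring, threshold
#' calibration (Otsu on the score histogram), activity classification,
#' sleep-bout calling, sleep metrics, centroid tracking and wake-gated
#' locomotion speed.
#'
#' @param config A [run_config].
#' @param input_dir Directory produced by [run_simulate()] (or holding
#'   equivalent single-well TIFFs).
#' @param track Also run centroid tracking (slower); `TRUE` by default.
#' @return A tibble with one row per well: sleep metrics plus
#'   `wake_speed_mm_s` and the calibrated `threshold`.
#' @export
run_score_larva <- function(config = run_config(), input_dir,
                            track = TRUE) {
  vids <- sort(list.files(input_dir, pattern = "^well_\\d+\\.tif$",
                          full.names = TRUE))
  if (length(vids) == 0L) {
    abort(sprintf("No well videos found in '%s'.", input_dir),
          class = "larvasleep_not_found")
  }
  rows <- map(vids, function(v) {
    stack <- read_frame_stack(v, fps = config$fps,
                              pixel_size_mm = config$pixel_size_mm)
    scores <- pixel_change_scores(stack, noise_floor = config$noise_floor)
    th <- calibrate_activity_threshold(scores)
    trace <- classify_activity(scores, th)
    bouts <- call_sleep_bouts(trace, config$min_sleep_frames)
    m <- sleep_metrics(trace, bouts)
    speed <- if (track) {
      tk <- track_centroids(stack, noise_floor = config$noise_floor)
      locomotion_speed(tk, bouts, fps = config$fps)$speed_mm_s
    } else {
      NA_real_
    }
    mutate(m, well_id = sub("\\.tif$", "", basename(v)), .before = 1) |>
      mutate(wake_speed_mm_s = speed, threshold = th)
  })
  list_rbind(rows)
}

#' Score every channel of a DAM monitor file
#'
#' @param config A [run_config].
#' @param dam_path Path to a DAM2 monitor text file.
#' @return Per-channel, per-day summary from [adult_sleep_summary()].
#' @export
run_score_adult <- function(config = run_config(), dam_path) {
  series <- parse_dam2(dam_path)
  bouts <- score_adult_sleep(series, config$adult_min_gap_min)
  n_days <- max(1L, floor(max(series$minute + 1L) / 1440L))
  adult_sleep_summary(bouts, n_days = n_days)
}

#' Compare metric tables between groups
#'
#' Binds named per-group metric tables and runs the declared comparisons
#' with Bonferroni adjustment (family = the declared comparison set).
#'
#' @param config A [run_config]; `config$comparisons`, when set, declares
#'   the comparison families.
#' @param metrics Named list of metrics tibbles (names are group labels),
#'   e.g. outputs of [run_score_larva()] per genotype.
#' @param value Metric column to compare (default `total_sleep_s`).
#' @return A comparison tibble from [compare_groups()].
#' @export
run_compare <- function(config = run_config(), metrics,
                        value = "total_sleep_s") {
  if (length(metrics) < 2L || is.null(names(metrics))) {
    abort("Need a named list of >= 2 metric tables.",
          class = "larvasleep_invalid_parameter")
  }
  data <- imap(metrics, function(tb, nm) mutate(tb, group = nm)) |>
    list_rbind()
  comparisons <- config$comparisons
  if (!is.null(comparisons)) comparisons <- map(comparisons, identity)
  compare_groups(data, value = value, group = "group",
                 comparisons = comparisons)
}
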