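# TriKinetics DAM2 monitor files: 1-min beam-crossing count bins, one row
# per reading, 42 tab-separated columns — reading index, date (d mmm yy),
# time (HH:MM:SS), status, six device/metadata fields, then counts for
# channels 1..32. Status 1 marks a valid reading; anything else flags the
# row as excluded from scoring.

DAM2_STATUS_VALID <- 1L
DAM2_META_COLS <- 6L
DAM2_CHANNELS <- 32L

#' Construct a DAM series
#'
#' Long-format container for per-minute beam-crossing counts: one row per
#' (minute bin, channel). `minute` is a 0-based index from the first
#' reading; `start_minute_of_day` anchors bins to clock time for
#' light/dark splitting.
#'
#' @param counts Tibble with columns `minute`, `channel`, `count`, `status`.
#' @param start_minute_of_day Clock minute (0–1439) of the first bin.
#' @param lights_on,lights_off Clock times of the LD cycle ("HH:MM");
#'   default 09:00 / 21:00.
#' @return A tibble of class `dam_series`.
#' @export
dam_series <- function(counts, start_minute_of_day = 540L,
                       lights_on = "09:00", lights_off = "21:00") {
  stopifnot(all(c("minute", "channel", "count", "status") %in% names(counts)))
  if (any(counts$count < 0, na.rm = TRUE)) {
    abort("Counts must be non-negative.",
          class = "larvasleep_invalid_parameter")
  }
  structure(as_tibble(counts),
            start_minute_of_day = as.integer(start_minute_of_day),
            lights_on = lights_on, lights_off = lights_off,
            class = c("dam_series", class(as_tibble(counts))))
}

#' Simulate a DAM beam-crossing series with a programmed sleep schedule
#'
#' Minutes inside the schedule are silent (count 0); minutes outside draw
#' from a zero-truncated Poisson (so a wake minute always registers at
#' least one crossing and the programmed schedule is exactly the set of
#' zero bins).
#'
#' @param sleep_schedule Tibble/data frame with `start_min`, `end_min`
#'   (0-based, half-open), disjoint and within `[0, n_minutes)`.
#' @param mean_counts_awake Mean of the (untruncated) Poisson wake law.
#' @param n_minutes Number of 1-min bins.
#' @param seed Integer seed.
#' @param channel Channel id to stamp on the series.
#' @param start_minute_of_day Clock minute of bin 0 (default 540 = 09:00,
#'   lights-on).
#' @return A [dam_series] carrying the schedule as ground truth.
#' @export
simulate_dam_series <- function(sleep_schedule, mean_counts_awake = 5,
                                n_minutes = 2880L, seed = 0L, channel = 1L,
                                start_minute_of_day = 540L) {
  assert_scalar_num(n_minutes, "n_minutes", min = 1)
  assert_scalar_num(mean_counts_awake, "mean_counts_awake", min = 0,
                    strict_min = TRUE)
  sched <- as_tibble(sleep_schedule)
  if (nrow(sched) > 0) {
    if (any(sched$start_min < 0) || any(sched$end_min > n_minutes) ||
        any(sched$end_min <= sched$start_min)) {
      abort("Schedule intervals must be non-empty and within [0, n_minutes).",
            class = "larvasleep_invalid_parameter")
    }
    s <- sched[order(sched$start_min), ]
    if (nrow(s) > 1 && any(s$start_min[-1] < s$end_min[-nrow(s)])) {
      abort("Schedule intervals overlap.",
            class = "larvasleep_invalid_parameter")
    }
  }
  asleep <- rep(FALSE, n_minutes)
  for (i in seq_len(nrow(sched))) {
    asleep[(sched$start_min[i] + 1):sched$end_min[i]] <- TRUE
  }
  counts <- with_seed(seed, {
    n_wake <- sum(!asleep)
    # zero-truncated Poisson via inverse CDF restricted to counts >= 1
    p0 <- stats::dpois(0, mean_counts_awake)
    u <- runif(n_wake, min = p0, max = 1)
    k <- integer(n_minutes)
    k[!asleep] <- qpois(u, mean_counts_awake)
    k
  })
  out <- dam_series(
    tibble(minute = seq_len(n_minutes) - 1L, channel = as.integer(channel),
           count = counts, status = DAM2_STATUS_VALID),
    start_minute_of_day = start_minute_of_day
  )
  attr(out, "ground_truth") <- list(sleep_schedule = sched,
                                    seed = as.integer(seed))
  out
}

#' Parse DAM2 monitor text
#'
#' @param text_lines Character vector of DAM2 lines (or a file path to a
#'   monitor file).
#' @return A [dam_series] covering all 32 channels. Rows whose status is
#'   not the valid code are retained with their status so the scorer can
#'   exclude them; a warning reports how many.
#' @export
parse_dam2 <- function(text_lines) {
  if (length(text_lines) == 1L && file.exists(text_lines)) {
    text_lines <- readLines(text_lines)
  }
  text_lines <- text_lines[nzchar(trimws(text_lines))]
  if (length(text_lines) == 0L) {
    abort("No DAM2 records found.", class = "larvasleep_format_error")
  }
  fields <- strsplit(text_lines, "\t", fixed = TRUE)
  ncol_exp <- 4L + DAM2_META_COLS + DAM2_CHANNELS
  nf <- lengths(fields)
  if (any(nf != ncol_exp)) {
    abort(sprintf("Line %d has %d fields; expected %d.",
                  which(nf != ncol_exp)[1], nf[nf != ncol_exp][1], ncol_exp),
          class = "larvasleep_format_error")
  }
  m <- do.call(rbind, fields)
  count_cols <- (4L + DAM2_META_COLS + 1L):ncol_exp
  counts <- suppressWarnings(matrix(as.numeric(m[, count_cols, drop = FALSE]),
                                    nrow = nrow(m)))
  bad <- which(rowSums(is.na(counts) |
                         counts != floor(counts)) > 0)
  if (length(bad) > 0) {
    abort(sprintf("Non-integer count field at line %d.", bad[1]),
          class = "larvasleep_parse_error")
  }
  status <- suppressWarnings(as.integer(m[, 4]))
  tmin <- vapply(m[, 3], function(s) {
    p <- as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
    p[1] * 60L + p[2]
  }, integer(1), USE.NAMES = FALSE)
  dayno <- match(m[, 2], unique(m[, 2]))   # lexical day grouping
  abs_min <- (dayno - 1L) * 1440L + tmin
  if (any(diff(abs_min) <= 0)) {
    abort("Timestamps are not strictly increasing.",
          class = "larvasleep_ordering_error")
  }
  n_excl <- sum(status != DAM2_STATUS_VALID)
  if (n_excl > 0) {
    warn(sprintf("Excluding %d row(s) with non-valid status from scoring.",
                 n_excl))
  }
  long <- tidyr::expand_grid(i = seq_len(nrow(m)),
                             channel = seq_len(DAM2_CHANNELS)) |>
    mutate(minute = abs_min[.data$i] - abs_min[1],
           count = counts[cbind(.data$i, .data$channel)],
           status = status[.data$i]) |>
    select("minute", "channel", "count", "status")
  dam_series(long, start_minute_of_day = tmin[1] %% 1440L)
}

#' Write a DAM series as DAM2 monitor text
#'
#' @param series A [dam_series] (channels absent from the series are
#'   written as zero).
#' @param path Output file; if `NULL`, the lines are returned invisibly.
#' @return The lines, invisibly.
#' @export
write_dam2 <- function(series, path = NULL) {
  wide <- series |>
    as_tibble() |>
    tidyr::pivot_wider(id_cols = c("minute", "status"),
                       names_from = "channel", values_from = "count",
                       values_fill = 0L)
  chans <- setdiff(as.character(seq_len(DAM2_CHANNELS)), names(wide))
  for (ch in chans) wide[[ch]] <- 0L
  start_mod <- attr(series, "start_minute_of_day") %||% 540L
  abs_min <- start_mod + wide$minute
  lines <- vapply(seq_len(nrow(wide)), function(i) {
    mm <- abs_min[i]
    day <- mm %/% 1440L
    tod <- mm %% 1440L
    paste(c(i,
            sprintf("%d Jan 24", 1L + day),
            sprintf("%02d:%02d:00", tod %/% 60L, tod %% 60L),
            wide$status[i],
            rep("0", DAM2_META_COLS),
            as.character(unlist(wide[i, as.character(seq_len(DAM2_CHANNELS))]))),
          collapse = "\t")
  }, character(1))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
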