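test_that("a 12-frame inactive run is one sleep bout with the right bounds", {
  tr <- trace_from_string(paste0(strrep("A", 5), strrep("I", 12),
                                 strrep("A", 5)))
  bouts <- call_sleep_bouts(tr)
  expect_equal(nrow(bouts), 1L)
  expect_equal(bouts$start_frame, 5L)
  expect_equal(bouts$end_frame, 17L)
  expect_equal(bouts$duration_s, 12 / 0.87)
})

test_that("all-active traces yield no bouts and edge runs count", {
  expect_equal(nrow(call_sleep_bouts(trace_from_string(strrep("A", 40)))), 0L)
  # runs truncated by the recording edges still count
  edge <- call_sleep_bouts(trace_from_string(paste0(strrep("I", 15),
                                                    strrep("A", 3),
                                                    strrep("I", 12))))
  expect_equal(edge$start_frame, c(0L, 18L))
  expect_equal(edge$end_frame, c(15L, 30L))
})

test_that("bout calling matches an independent run-length oracle", {
  set.seed(10)
  for (i in 1:300) {
    states <- random_states(sample(5:80, 1), runif(1, 0.2, 0.8))
    mf <- sample(1:15, 1)
    got <- call_sleep_bouts(behavior_trace(states), min_frames = mf)
    expect_equal(as.data.frame(got[, 1:2]),
                 rle_oracle(states, min_len = mf),
                 ignore_attr = TRUE)
  }
})

test_that("sleep plus wake always partitions the analysis window", {
  set.seed(3)
  for (i in 1:50) {
    tr <- behavior_trace(random_states(sample(50:400, 1)))
    fps <- 0.87
    rec <- nrow(tr) / fps
    w0 <- runif(1, 0, rec / 2); w1 <- runif(1, w0 + 1, rec)
    m <- sleep_metrics(tr, window = c(w0, w1))
    expect_equal(m$total_sleep_s + m$total_wake_s, w1 - w0)
  }
})

test_that("sleep metrics match a brute-force per-frame summation", {
  set.seed(8)
  fps <- 0.87
  for (i in 1:30) {
    states <- random_states(200)
    tr <- behavior_trace(states, fps = fps)
    bouts <- call_sleep_bouts(tr, min_frames = 12)
    m <- sleep_metrics(tr, bouts)
    in_bout <- rep(FALSE, 200)
    for (j in seq_len(nrow(bouts))) {
      in_bout[(bouts$start_frame[j] + 1):bouts$end_frame[j]] <- TRUE
    }
    expect_equal(m$total_sleep_s, sum(in_bout) / fps)
  }
})

test_that("metric edge cases follow their contracts", {
  tr <- trace_from_string(strrep("A", 100))
  m <- sleep_metrics(tr)
  expect_equal(m$total_sleep_s, 0)
  expect_true(is.na(m$sleep_latency_s))
  expect_equal(m$bout_count, 0L)

  one <- trace_from_string(strrep("I", 200))
  m1 <- sleep_metrics(one)
  expect_equal(m1$total_sleep_s, 200 / 0.87)
  expect_equal(m1$sleep_latency_s, 0)
  expect_error(sleep_metrics(tr, window = c(-1, 10)),
               class = "larvasleep_invalid_parameter")
})

test_that("raising min_frames never increases total sleep", {
  set.seed(5)
  for (i in 1:20) {
    tr <- behavior_trace(random_states(300))
    totals <- vapply(c(1, 6, 12, 20, 40), function(mf) {
      sleep_metrics(tr, min_frames = mf)$total_sleep_s
    }, numeric(1))
    expect_true(all(diff(totals) <= 1e-12))
  }
})

make_track <- function(xy, valid = NULL) {
  structure(tibble::tibble(frame = seq_len(nrow(xy)) - 1L,
                           x_mm = xy[, 1], y_mm = xy[, 2],
                           valid = valid %||% rep(TRUE, nrow(xy))),
            units = "mm",
            class = c("centroid_track", "tbl_df", "tbl", "data.frame"))
}

test_that("locomotion speed has its closed-form values", {
  fps <- 0.87
  still <- make_track(cbind(rep(1, 50), rep(2, 50)))
  expect_equal(locomotion_speed(still, fps = fps)$speed_mm_s, 0)

  d <- 0.4
  moving <- make_track(cbind(cumsum(rep(d, 60)), rep(0, 60)))
  expect_equal(locomotion_speed(moving, fps = fps)$speed_mm_s, d * fps)
})

test_that("locomotion speed is invariant to inserted sleep frames", {
  fps <- 0.87
  set.seed(2)
  wake_xy <- cbind(cumsum(runif(40, 0, 0.5)), cumsum(runif(40, 0, 0.5)))
  base <- locomotion_speed(make_track(wake_xy), fps = fps)$speed_mm_s
  # freeze the animal for 30 frames in the middle; bouts mark them as sleep
  ins <- rbind(wake_xy[1:20, ],
               matrix(rep(wake_xy[20, ], each = 30), 30),
               wake_xy[21:40, ])
  bouts <- structure(tibble::tibble(start_frame = 20L, end_frame = 50L,
                                    duration_s = 30 / fps),
                    fps = fps,
                    class = c("sleep_bouts", "tbl_df", "tbl", "data.frame"))
  with_sleep <- locomotion_speed(make_track(ins), bouts,
                                 fps = fps)$speed_mm_s
  expect_equal(with_sleep, base)
})

test_that("invalid-tracking frames drop from both speed terms", {
  fps <- 1
  xy <- cbind(c(0, 1, 2, 10, 11), rep(0, 5))
  valid <- c(TRUE, TRUE, TRUE, FALSE, TRUE)
  # steps 0->1, 1->2 count; steps touching the invalid frame do not
  sp <- locomotion_speed(make_track(xy, valid), fps = fps)
  expect_equal(sp$distance_mm, 2)
  expect_equal(sp$wake_time_s, 2)

  all_sleep <- structure(tibble::tibble(start_frame = 0L, end_frame = 5L,
                                        duration_s = 5),
                         fps = fps,
                         class = c("sleep_bouts", "tbl_df", "tbl",
                                   "data.frame"))
  expect_warning(out <- locomotion_speed(make_track(xy), all_sleep,
                                         fps = fps),
                 "undefined")
  expect_true(is.na(out$speed_mm_s))
})

test_that("light-response and rebound indices follow their definitions", {
  expect_equal(light_response_index(1800, 3600), 0.5)
  expect_equal(light_response_index(1200, 1200), 1)
  expect_warning(expect_true(is.na(light_response_index(100, 0))))
  expect_error(light_response_index(-1, 10),
               class = "larvasleep_invalid_parameter")

  expect_equal(rebound_index(600, 900), 1.5)
  expect_equal(rebound_index(700, 700), 1)
  expect_warning(expect_true(is.na(rebound_index(0, 100))))
})

test_that("a 1.4x post-deprivation cohort recovers a median rebound near 1.4", {
  idx <- vapply(1:40, function(seed) {
    pre <- simulate_behavior_trace(duration_s = 3600, mean_wake_s = 120,
                                   mean_sleep_s = 60, seed = seed)
    post <- simulate_behavior_trace(duration_s = 3600, mean_wake_s = 120,
                                    mean_sleep_s = 105, seed = 1000 + seed)
    rebound_index(sleep_metrics(pre, min_frames = 1)$total_sleep_s,
                  sleep_metrics(post, min_frames = 1)$total_sleep_s)
  }, numeric(1))
  med <- median(idx)
  ci_half <- 1.96 * 1.2533 * stats::sd(idx) / sqrt(length(idx))
  expect_lt(abs(med - 1.4), ci_half + 0.1)
})

test_that("the deprivation schedule realises the 90/30 cycle protocol", {
  sched <- deprivation_schedule()
  expect_equal(nrow(sched), 30L)
  expect_equal(sched$on_start_s[1], 3600)
  expect_equal(sched$on_end_s[1], 3690)
  expect_true(all(sched$on_end_s - sched$on_start_s == 90))
  expect_equal(sum(sched$on_end_s - sched$on_start_s), 2700)
  # disjoint, sorted, separated by the OFF period
  expect_true(all(diff(sched$on_start_s) == 120))

  expect_equal(nrow(deprivation_schedule(session_s = 0)), 0L)

  trunc <- deprivation_schedule(baseline_s = 100, on_s = 90, off_s = 30,
                                session_s = 200)
  expect_equal(trunc$on_start_s, c(100, 220))
  expect_equal(trunc$on_end_s, c(190, 300))
  expect_error(deprivation_schedule(on_s = 0, off_s = 0, session_s = 10),
               class = "larvasleep_invalid_parameter")
})
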