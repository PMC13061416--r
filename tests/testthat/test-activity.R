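test_that("pixel-change scores follow their counting definition", {
  # identical frames -> 0
  arr <- array(100, dim = c(10, 10, 3))
  stk <- frame_stack(arr, fps = 1)
  expect_true(all(pixel_change_scores(stk, noise_floor = 5)$score == 0))

  # exactly k pixels changed beyond the floor -> score k
  arr2 <- arr
  arr2[1:3, 1, 2] <- 150
  sc <- pixel_change_scores(frame_stack(arr2, fps = 1), noise_floor = 5)
  expect_equal(sc$score[2], 3)
  # frame 0 copies frame 1
  expect_equal(sc$score[1], sc$score[2])
})

test_that("scores equal a naive per-pixel double loop on small stacks", {
  set.seed(42)
  for (rep in 1:3) {
    arr <- array(sample(0:255, 20 * 20 * 10, TRUE), dim = c(20, 20, 10))
    floor <- sample(c(0, 5, 20), 1)
    sc <- pixel_change_scores(frame_stack(arr, fps = 1),
                              noise_floor = floor)$score
    oracle <- numeric(10)
    for (t in 2:10) {
      cnt <- 0
      for (i in 1:20) for (j in 1:20) {
        if (abs(arr[i, j, t] - arr[i, j, t - 1]) > floor) cnt <- cnt + 1
      }
      oracle[t] <- cnt
    }
    oracle[1] <- oracle[2]
    expect_identical(sc, oracle)
  }
})

test_that("immobile-larva scores sit below the calibrated threshold", {
  states <- rep(rep(c("active", "inactive"), 6), each = 10)
  mixed <- tiny_video(states, seed = 3)
  th <- calibrate_activity_threshold(pixel_change_scores(mixed))
  quiet <- tiny_video(rep("inactive", 120), seed = 4)
  q99 <- quantile(pixel_change_scores(quiet)$score, 0.99)
  expect_lt(q99, th)
})

test_that("threshold calibration separates two score clusters", {
  scores <- c(rnorm(100, 5, 1), rnorm(100, 60, 5))
  th <- calibrate_activity_threshold(scores)
  expect_gt(th, max(scores[1:100]))
  expect_lt(th, min(scores[101:200]))
})

test_that("labeled calibration maximises accuracy (brute-force sweep oracle)", {
  set.seed(7)
  scores <- c(rnorm(80, 10, 3), rnorm(80, 30, 8))
  labels <- rep(c("inactive", "active"), each = 80)
  th <- calibrate_activity_threshold(scores, labels)
  acc_at <- function(t) mean((scores > t) == (labels == "active"))
  # exhaustive scan over every candidate midpoint
  ux <- sort(unique(scores))
  cands <- c(ux[1] - 1, (ux[-1] + ux[-length(ux)]) / 2, ux[length(ux)] + 1)
  expect_equal(acc_at(th), max(vapply(cands, acc_at, numeric(1))))

  # perfectly separable labels reach accuracy 1
  sep <- c(1:50, 101:150)
  lab <- rep(c("inactive", "active"), each = 50)
  expect_equal(acc_at2 <- mean((sep > calibrate_activity_threshold(sep, lab)) ==
                                 (lab == "active")), 1)
})

test_that("calibration input contracts hold", {
  expect_error(calibrate_activity_threshold(rnorm(50)),
               class = "larvasleep_invalid_parameter")
  expect_error(calibrate_activity_threshold(rep(1, 200)),
               class = "larvasleep_degenerate_input")
  expect_error(calibrate_activity_threshold(rnorm(200),
                                            rep("active", 200)),
               class = "larvasleep_invalid_parameter")
})

test_that("classification is strict and tie-breaks toward quiescence", {
  sc <- structure(tibble::tibble(frame = 0:4,
                                 score = c(0, 0, 5, 5.0001, 10)),
                  fps = 1, class = c("activity_scores", "tbl_df",
                                     "tbl", "data.frame"))
  tr <- classify_activity(sc, threshold = 5)
  expect_equal(tr$state, c("inactive", "inactive", "inactive",
                           "active", "active"))
  tr0 <- classify_activity(sc, threshold = 0)
  expect_equal(tr0$state[1:2], c("inactive", "inactive"))
})

test_that("raising the threshold never converts inactive frames to active", {
  set.seed(1)
  sc <- structure(tibble::tibble(frame = 0:199,
                                 score = rpois(200, 20)),
                  fps = 1, class = c("activity_scores", "tbl_df",
                                     "tbl", "data.frame"))
  prev <- classify_activity(sc, 0)$state
  for (th in c(5, 10, 20, 40)) {
    cur <- classify_activity(sc, th)$state
    expect_true(all(!(prev == "inactive" & cur == "active")))
    prev <- cur
  }
})

test_that("centroid tracking recovers a static symmetric blob", {
  arr <- array(200, dim = c(100, 100, 6))
  for (t in 1:6) arr[46:56, 46:56, t] <- 60   # 0-based centre (50, 50)
  stk <- frame_stack(arr, fps = 1)
  trk <- track_centroids(stk, noise_floor = 10)
  expect_true(all(abs(trk$x_px - 50) < 0.5))
  expect_true(all(abs(trk$y_px - 50) < 0.5))
  expect_true(all(trk$valid))
})

test_that("an empty well raises a dedicated error", {
  set.seed(2)
  arr <- array(pmin(255, pmax(0, round(rnorm(40 * 40 * 10, 200, 1)))),
               dim = c(40, 40, 10))
  expect_error(track_centroids(frame_stack(arr, fps = 1), noise_floor = 15),
               class = "larvasleep_empty_well")
})

test_that("tracking follows the programmed trajectory within 1 px", {
  tr <- behavior_trace(rep(c("active", "inactive"),
                           times = c(120, 80)))
  stk <- render_larva_video(tr, motion = motion_params(noise_sd = 0),
                            well_size_px = c(100, 100), seed = 6)
  trk <- track_centroids(stk, noise_floor = 10)
  truth <- ground_truth(stk)$path
  px <- attr(stk, "pixel_size_mm")
  err <- sqrt((trk$x_mm - truth$x_mm)^2 + (trk$y_mm - truth$y_mm)^2) / px
  expect_true(all(err <= 1))
})

test_that("classifying one well is unaffected by other wells (order-free)", {
  # build a 1 x 2 arena from two independent wells
  a <- tiny_video(rep(c("active", "inactive"), each = 30), seed = 1,
                  well = c(60, 60))
  b <- tiny_video(rep(c("inactive", "active"), each = 30), seed = 2,
                  well = c(60, 60))
  arena_ab <- frame_stack(abind_cols(unclass(a), unclass(b)), fps = 0.87)
  arena_ba <- frame_stack(abind_cols(unclass(b), unclass(a)), fps = 0.87)
  grid <- detect_wells(arena_ab[, , 1], rows = 1, cols = 2)
  th <- 25
  s_ab <- pixel_change_scores(arena_ab, grid[1, ], noise_floor = 10)
  s_ba <- pixel_change_scores(arena_ba, grid[2, ], noise_floor = 10)
  expect_identical(classify_activity(s_ab, th)$state,
                   classify_activity(s_ba, th)$state)
})
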