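test_that("separated samples give U = 0 and exact p = 0.1", {
  cmp <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 0.1)   # 2 * 1/20 orderings
  expect_equal(cmp$mode, "exact")
})

test_that("identical samples give the midpoint U and p near 1", {
  x <- c(2, 4, 6, 8, 10)
  cmp <- mann_whitney_u(x, x)
  expect_equal(cmp$statistic, length(x)^2 / 2)
  expect_gt(cmp$p_value, 0.9)
})

test_that("exact p values agree with the independent enumeration oracle", {
  set.seed(21)
  for (i in 1:300) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    x <- rnorm(n); y <- rnorm(m, sample(c(0, 1.5), 1))
    cmp <- mann_whitney_u(x, y)
    expect_equal(cmp$mode, "exact")
    oracle <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(cmp$statistic, unname(oracle$statistic))
    expect_equal(cmp$p_value, oracle$p.value, tolerance = 1e-12)
  }
})

test_that("the approximate p matches the reference tie-corrected normal test", {
  set.seed(22)
  for (i in 1:100) {
    n <- sample(9:30, 1); m <- sample(9:30, 1)
    x <- round(rnorm(n, 0, 2), 1); y <- round(rnorm(m, 0.5, 2), 1)
    cmp <- mann_whitney_u(x, y, mode = "approx")
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("swapping groups maps U to nm - U and preserves p", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(3:12, 1); m <- sample(3:12, 1)
    x <- rnorm(n); y <- rnorm(m, 0.8)
    a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
    expect_equal(a$statistic + b$statistic, n * m)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  }
})

test_that("empty groups and exact-with-ties are rejected", {
  expect_error(mann_whitney_u(numeric(0), 1:3),
               class = "larvasleep_invalid_parameter")
  expect_error(mann_whitney_u(c(1, 1, 2), c(1, 3), mode = "exact"),
               class = "larvasleep_invalid_parameter")
})

test_that("Kruskal-Wallis H matches manual rank arithmetic and the reference", {
  # enumerable 3-group example: pooled ranks are 1..9
  g <- list(a = c(1, 4, 7), b = c(2, 5, 8), c = c(3, 6, 9))
  ranksums <- c(1 + 4 + 7, 2 + 5 + 8, 3 + 6 + 9)
  h_manual <- 12 / (9 * 10) * sum(ranksums^2 / 3) - 3 * 10
  cmp <- kruskal_wallis(g)
  expect_equal(cmp$statistic, h_manual)

  set.seed(24)
  for (i in 1:50) {
    gs <- purrr::map(1:sample(2:4, 1) + 1, ~round(rnorm(sample(5:15, 1)), 1))
    ref <- stats::kruskal.test(gs)
    cmp <- kruskal_wallis(gs)
    expect_equal(cmp$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("all-tied groups give an undefined Kruskal-Wallis statistic", {
  expect_warning(cmp <- kruskal_wallis(list(rep(3, 5), rep(3, 4))),
                 "undefined")
  expect_true(is.na(cmp$statistic))
  expect_error(kruskal_wallis(list(1:5)),
               class = "larvasleep_invalid_parameter")
})

test_that("two-group Kruskal-Wallis approximates the U test at large n", {
  set.seed(25)
  x <- rnorm(25); y <- rnorm(25, 0.4)
  p_kw <- kruskal_wallis(list(x, y))$p_value
  p_mw <- mann_whitney_u(x, y, mode = "approx")$p_value
  expect_lt(abs(p_kw - p_mw), 0.01)
})

test_that("chi-square follows the closed-form Pearson statistic", {
  flat <- chi_square(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  diag <- chi_square(matrix(c(20, 0, 0, 20), 2))
  expect_equal(diag$statistic, 40)

  set.seed(26)
  for (i in 1:100) {
    tab <- matrix(sample(10:40, 4, TRUE), 2)
    cmp <- chi_square(tab)
    rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
    exp_tab <- outer(rs, cs) / N
    expect_equal(cmp$statistic, sum((tab - exp_tab)^2 / exp_tab),
                 tolerance = 1e-12)
    ref <- stats::chisq.test(tab, correct = FALSE)
    expect_equal(cmp$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(chi_square(matrix(c(1, 0, 2, 0), 2, byrow = TRUE)),
               class = "larvasleep_invalid_parameter")
})

test_that("Bonferroni scales, caps, preserves order and never shrinks p", {
  expect_equal(bonferroni(0.01, family_size = 5), 0.05)
  expect_equal(bonferroni(0.5, family_size = 3), 1)
  expect_equal(bonferroni(c(0.2, 0.03), family_size = 1), c(0.2, 0.03))
  set.seed(27)
  p <- runif(20)
  adj <- bonferroni(p, family_size = 7)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_equal(bonferroni(p, family_size = length(p)),
               stats::p.adjust(p, "bonferroni"))
  expect_error(bonferroni(c(0.1, 1.2)),
               class = "larvasleep_invalid_parameter")
})

test_that("median/IQR summaries use the interpolated quartile convention", {
  s <- summarize_median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(c(s$median, s$q1, s$q3), c(3, 2, 4))
  s1 <- summarize_median_iqr(7)
  expect_equal(c(s1$median, s1$q1, s1$q3), c(7, 7, 7))
  set.seed(28)
  for (i in 1:30) {
    v <- rnorm(sample(2:40, 1))
    s <- summarize_median_iqr(v)
    # sort-and-interpolate oracle (type-7 positions 1 + (n-1) p)
    srt <- sort(v); n <- length(v)
    interp <- function(p) {
      h <- 1 + (n - 1) * p
      lo <- floor(h)
      srt[lo] + (h - lo) * (srt[min(lo + 1, n)] - srt[lo])
    }
    expect_equal(c(s$q1, s$median, s$q3),
                 c(interp(0.25), interp(0.5), interp(0.75)))
  }
  expect_error(summarize_median_iqr(numeric(0)),
               class = "larvasleep_invalid_parameter")
})

test_that("tidy and glance return one-row summaries", {
  cmp <- mann_whitney_u(rnorm(5), rnorm(5))
  td <- tidy(cmp)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_true(all(c("statistic", "p_value", "method") %in% names(td)))
  expect_equal(glance(cmp)$statistic, td$statistic)
})

test_that("compare_groups runs declared families with adjusted p values", {
  set.seed(29)
  df <- tibble::tibble(
    sleep = c(rnorm(15, 10), rnorm(15, 10), rnorm(15, 14)),
    genotype = rep(c("control", "mutA", "mutB"), each = 15))
  out <- compare_groups(df, "sleep", "genotype")
  expect_equal(nrow(out), 2L)
  expect_equal(out$p_adjusted, pmin(1, out$p_value * 2))
  expect_true(out$p_value[out$group_b == "mutB"] < 0.05)
  expect_true(all(c("median_a", "q1_b", "q3_b") %in% names(out)))
})

test_that("a trace-level two-genotype experiment detects a 30% sleep increase", {
  n_reject <- 0
  for (seed in 1:10) {
    mk <- function(mean_sleep, off) {
      purrr::map(1:20, function(i) {
        tr <- simulate_behavior_trace(duration_s = 3600, mean_wake_s = 90,
                                      mean_sleep_s = mean_sleep,
                                      seed = off + seed * 100 + i)
        sleep_metrics(tr)
      }) |> purrr::list_rbind()
    }
    # control sleeps 40% of the time; the mutant generator adds 30% sleep
    # (fraction 0.52), i.e. mean sleep bout 97.5 s against the same wake law
    metrics <- list(control = mk(60, 0), mutant = mk(97.5, 5e5))
    out <- run_compare(run_config(), metrics)
    if (out$p_adjusted < 0.05 &&
        out$median_b > out$median_a) n_reject <- n_reject + 1
  }
  expect_gte(n_reject, 9)
})
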