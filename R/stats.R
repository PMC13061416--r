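# Nonparametric group comparisons: Mann-Whitney U (exact by enumeration for
# small tie-free samples, tie/continuity-corrected normal approximation
# otherwise), tie-corrected Kruskal-Wallis, Pearson chi-square, Bonferroni
# adjustment, and median/IQR summaries. The authored implementations are
# cross-checked against stats::wilcox.test / kruskal.test / chisq.test in
# the test suite.

new_group_comparison <- function(method, statistic, p_value, n, summary,
                                 mode = NA_character_) {
  structure(list(method = method, statistic = statistic,
                 p_value = p_value, p_adjusted = NA_real_, n = n,
                 summary = summary, mode = mode),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g%s\n", x$method, x$statistic,
              x$p_value,
              if (!is.na(x$p_adjusted)) sprintf(" (adj. %.4g)", x$p_adjusted)
              else ""))
  print(x$summary)
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `statistic`, `p_value`,
#'   `p_adjusted` and sample sizes.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p_value = x$p_value,
         p_adjusted = x$p_adjusted,
         n = paste(x$n, collapse = ","), mode = x$mode)
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) tidy(x, ...)

#' Median and quartile summary
#'
#' The per-group summary used throughout: median and interquartile range
#' (Q1–Q3), quartiles by the linear-interpolation (type 7) convention.
#'
#' @param values Numeric vector with at least one value.
#' @return A one-row tibble: `n`, `median`, `q1`, `q3`.
#' @export
summarize_median_iqr <- function(values) {
  if (length(values) < 1L || !is.numeric(values)) {
    abort("Need at least one numeric value.",
          class = "larvasleep_invalid_parameter")
  }
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble(n = length(values), median = q[2], q1 = q[1], q3 = q[3])
}

group_summary <- function(groups) {
  imap(groups, function(v, nm) mutate(summarize_median_iqr(v),
                                      group = nm, .before = 1)) |>
    list_rbind()
}

# Exact null distribution of U for group sizes (n, m): counts over all
# C(n + m, n) assignments of ranks to the first group.
u_exact_distribution <- function(n, m) {
  ranks <- combn(n + m, n)
  u <- colSums(ranks) - n * (n + 1) / 2
  tabulate(u + 1L, nbins = n * m + 1L)   # counts for U = 0..n*m
}

#' Mann–Whitney U test
#'
#' Two-sided rank-sum test. The U statistic is computed from midranks of
#' the pooled sample. With `mode = "auto"` the p value is exact — by full
#' enumeration of all rank assignments — when both groups have at most 8
#' observations and there are no ties; otherwise a normal approximation
#' with tie correction and continuity correction is used (exact
#' enumeration under ties is not attempted). The exact two-sided p value
#' is the doubled one-sided tail, capped at 1.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return A `group_comparison` object; `tidy()` it for a tabular row.
#' @examples
#' mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' tidy(mw)   # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L || anyNA(c(x, y))) {
    abort("Both groups must be non-empty and free of missing values.",
          class = "larvasleep_invalid_parameter")
  }
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  use_exact <- switch(mode,
                      exact = TRUE,
                      approx = FALSE,
                      auto = n <= 8 && m <= 8 && !has_ties)
  if (use_exact && has_ties) {
    abort("Exact mode is unavailable with ties; use mode = \"approx\".",
          class = "larvasleep_invalid_parameter")
  }
  if (use_exact) {
    dist <- u_exact_distribution(n, m)
    total <- sum(dist)
    p_lo <- sum(dist[seq_len(u + 1L)]) / total          # P(U <= u)
    p_hi <- sum(dist[(u + 1L):(n * m + 1L)]) / total    # P(U >= u)
    p <- min(1, 2 * min(p_lo, p_hi))
    used <- "exact"
  } else {
    mu <- n * m / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n * m / 12 *
      ((n + m + 1) - tie_term / ((n + m) * (n + m - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
      p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
    }
    used <- "normal_approx"
  }
  new_group_comparison("Mann-Whitney U", statistic = u, p_value = p,
                       n = c(n, m),
                       summary = group_summary(list(x = x, y = y)),
                       mode = used)
}

#' Kruskal–Wallis rank test
#'
#' H statistic from midranks with tie correction; p value from the
#' chi-square tail with k − 1 degrees of freedom. When every pooled value
#' is identical the statistic is degenerate (the tie correction removes
#' all rank variance) and `NA` is returned with a warning.
#'
#' @param groups A list of 2 or more non-empty numeric vectors.
#' @return A `group_comparison` object.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L ||
      any(lengths(groups) == 0L)) {
    abort("Need a list of >= 2 non-empty groups.",
          class = "larvasleep_invalid_parameter")
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  grp <- rep(seq_along(groups), lengths(groups))
  rank_sums <- tapply(r, grp, sum)
  h <- 12 / (N * (N + 1)) * sum(rank_sums^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(pooled)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (correction == 0) {
    warn("All values tie; the Kruskal-Wallis statistic is undefined.")
    h <- NA_real_; p <- NA_real_
  } else {
    h <- h / correction
    p <- pchisq(h, df = length(groups) - 1L, lower.tail = FALSE)
  }
  new_group_comparison("Kruskal-Wallis", statistic = h, p_value = p,
                       n = lengths(groups),
                       summary = group_summary(groups))
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic without continuity correction; p from the chi-square
#' tail with (r − 1)(c − 1) degrees of freedom.
#'
#' @param table A 2-D matrix of non-negative counts with all row and
#'   column sums positive.
#' @return A `group_comparison` object.
#' @export
chi_square <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || nrow(tab) < 2L || ncol(tab) < 2L) {
    abort("Need an r x c table (r, c >= 2) of non-negative counts.",
          class = "larvasleep_invalid_parameter")
  }
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    abort("All marginal sums must be positive.",
          class = "larvasleep_invalid_parameter")
  }
  expected <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  new_group_comparison("Pearson chi-square", statistic = stat,
                       p_value = pchisq(stat, df, lower.tail = FALSE),
                       n = sum(tab),
                       summary = tibble(df = df))
}

#' Bonferroni adjustment
#'
#' Each p value is multiplied by the declared family size and capped at 1.
#' The family is the set of planned comparisons within one panel and must
#' be declared explicitly — it is never inferred from the vector length
#' unless left at the default.
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @param family_size Number of comparisons in the family (default
#'   `length(p_values)`).
#' @return Adjusted p values, in the input order.
#' @export
bonferroni <- function(p_values, family_size = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p values must lie in [0, 1].",
          class = "larvasleep_invalid_parameter")
  }
  assert_scalar_num(family_size, "family_size", min = 1)
  pmin(1, family_size * p_values)
}

#' Compare groups in a metrics table
#'
#' Tidy front end to [mann_whitney_u()]: runs every declared pairwise
#' comparison on one metric column and Bonferroni-adjusts within the
#' declared family.
#'
#' @param data A data frame of per-animal metrics.
#' @param value Name of the metric column.
#' @param group Name of the grouping column.
#' @param comparisons List of length-2 character vectors (pairs of group
#'   labels); default: every group against the first.
#' @param family_size Bonferroni family size; defaults to the number of
#'   comparisons.
#' @return A tibble with one row per comparison: group labels, sample
#'   sizes, U, p, adjusted p, and per-group median/Q1/Q3.
#' @export
compare_groups <- function(data, value, group, comparisons = NULL,
                           family_size = NULL) {
  vals <- data[[value]]; grp <- as.character(data[[group]])
  levels <- unique(grp)
  if (is.null(comparisons)) {
    if (length(levels) < 2L) {
      abort("Need at least two groups.",
            class = "larvasleep_invalid_parameter")
    }
    comparisons <- map(levels[-1], function(g) c(levels[1], g))
  }
  family_size <- family_size %||% length(comparisons)
  rows <- map(comparisons, function(pair) {
    xa <- vals[grp == pair[1]]; xb <- vals[grp == pair[2]]
    if (length(xa) == 0L || length(xb) == 0L) {
      abort(sprintf("Empty group in comparison %s vs %s.",
                    pair[1], pair[2]),
            class = "larvasleep_invalid_parameter")
    }
    cmp <- mann_whitney_u(xa, xb)
    sa <- summarize_median_iqr(xa); sb <- summarize_median_iqr(xb)
    tibble(group_a = pair[1], group_b = pair[2],
           n_a = length(xa), n_b = length(xb),
           statistic = cmp$statistic, p_value = cmp$p_value,
           median_a = sa$median, q1_a = sa$q1, q3_a = sa$q3,
           median_b = sb$median, q1_b = sb$q1, q3_b = sb$q3)
  })
  list_rbind(rows) |>
    mutate(p_adjusted = bonferroni(.data$p_value, family_size),
           .after = "p_value")
}
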