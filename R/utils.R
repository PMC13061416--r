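# Internal helpers shared across modules.

assert_scalar_num <- function(x, name, min = -Inf, max = Inf,
                              strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "larvasleep_invalid_parameter")
  }
  bad_low <- if (strict_min) x <= min else x < min
  if (bad_low || x > max) {
    abort(sprintf("`%s` must be in [%s, %s]%s.", name,
                  if (strict_min) paste0("(", min) else min, max,
                  if (strict_min) " (exclusive lower bound)" else ""),
          class = "larvasleep_invalid_parameter")
  }
  invisible(x)
}

# Maximal runs of `states == target`, as 0-based half-open frame intervals.
# This is the single run-length primitive behind bout calling and ground truth.
runs_of <- function(states, target = "inactive") {
  if (length(states) == 0L) {
    return(tibble(start_frame = integer(), end_frame = integer()))
  }
  r <- rle(states == target)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble(start_frame = as.integer(starts[r$values]),
         end_frame = as.integer(ends[r$values]))
}

# Otsu's method on a numeric vector: the threshold (a midpoint between two
# adjacent observed values) maximising between-class variance of the split
# x <= t vs x > t. Deterministic; errors on degenerate (constant) input.
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  ux <- sort(unique(x))
  if (length(ux) < 2L) {
    abort("All values are identical; no threshold separates two classes.",
          class = "larvasleep_degenerate_input")
  }
  xs <- sort(x)
  n <- length(xs)
  cand <- (ux[-length(ux)] + ux[-1L]) / 2
  # counts and sums below each candidate
  idx <- findInterval(cand, xs)          # number of values <= cand
  csum <- cumsum(xs)
  n0 <- idx
  n1 <- n - n0
  mu0 <- csum[idx] / n0
  mu1 <- (csum[n] - csum[idx]) / n1
  between <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
  cand[which.max(between)]
}

# Clip to 8-bit and round; used by every renderer that emits camera frames.
clip8 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  round(x)
}

with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single integer.",
          class = "larvasleep_invalid_parameter")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

parse_clock_min <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  as.integer(parts[1]) * 60L + as.integer(parts[2])
}
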