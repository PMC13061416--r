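# Shared fixture builders and independent oracles. Oracles here are written
# as plain loops so they share no code path with the implementation.

`%||%` <- function(a, b) if (is.null(a)) b else a

# "AAIIA" -> behavior trace
trace_from_string <- function(s, fps = 0.87) {
  states <- ifelse(strsplit(s, "")[[1]] == "A", "active", "inactive")
  behavior_trace(states, fps = fps)
}

# Independent run-length scan: maximal runs of `target` as 0-based
# half-open intervals, found by a per-element loop.
rle_oracle <- function(states, target = "inactive", min_len = 1L) {
  starts <- integer(0); ends <- integer(0)
  in_run <- FALSE; s0 <- 0L
  for (i in seq_along(states)) {
    if (states[i] == target && !in_run) {
      in_run <- TRUE; s0 <- i - 1L
    }
    if (states[i] != target && in_run) {
      in_run <- FALSE
      if ((i - 1L) - s0 >= min_len) {
        starts <- c(starts, s0); ends <- c(ends, i - 1L)
      }
    }
  }
  if (in_run && length(states) - s0 >= min_len) {
    starts <- c(starts, s0); ends <- c(ends, length(states))
  }
  data.frame(start_frame = starts, end_frame = ends)
}

random_states <- function(n, p_inactive = 0.5) {
  ifelse(runif(n) < p_inactive, "inactive", "active")
}

# Bind two H x W x T arrays side by side (shared H and T)
abind_cols <- function(a, b) {
  H <- dim(a)[1]; T_ <- dim(a)[3]
  out <- array(0, dim = c(H, dim(a)[2] + dim(b)[2], T_))
  out[, seq_len(dim(a)[2]), ] <- a
  out[, dim(a)[2] + seq_len(dim(b)[2]), ] <- b
  out
}

# Small all-state video for fast classifier tests
tiny_video <- function(states, noise_sd = 2, seed = 1,
                       well = c(60, 60), speed = 0.3) {
  tr <- behavior_trace(states)
  render_larva_video(tr,
                     motion = motion_params(noise_sd = noise_sd,
                                            crawl_speed_mean = speed),
                     well_size_px = well, seed = seed)
}
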