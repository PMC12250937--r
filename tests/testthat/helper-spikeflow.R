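# Shared fixtures, built in code at test time.

hp20 <- function() quantize_biquad(design_highpass_butterworth(20000, 300))

# A random raw sample matrix for codec fuzzing: mixes extremes and
# sync-fragment byte patterns with ordinary values.
random_samples <- function(n_frames, n_tot) {
  pool <- c(-32768L, 32767L, 0L, -1L, 1L,
            -6703L, 23063L,  # int16 views of sync words 0xE5D1, 0x5A17
            sample.int(65536L, 64L) - 32768L)
  matrix(sample(pool, n_frames * n_tot, replace = TRUE),
         nrow = n_frames, ncol = n_tot)
}

# A single-channel trace (in counts) with noise plus a few large
# negative-going deflections; guaranteed int16-safe.
random_spiky_trace <- function(n, sigma = 80, n_spikes = 5,
                               amp_counts = -700) {
  x <- round(rnorm(n, 0, sigma))
  if (n_spikes > 0 && n > 80) {
    at <- sort(sample(10:(n - 10), n_spikes))
    x[at] <- x[at] + amp_counts
  }
  as.integer(pmin(pmax(x, -32767), 32767))
}

# Left-fold of the pure-R detector step: the independent oracle for the
# compiled batch detector.
detect_fold_r <- function(filtered, cfg) {
  st <- detector_state_init()
  ev <- numeric(0)
  for (i in seq_along(filtered)) {
    r <- detect_step(st, filtered[i], cfg)
    st <- r$state
    if (r$spike) ev <- c(ev, i - 2)  # peak is the previous sample, 0-based
  }
  ev
}

# Left-fold of the pure-R biquad step.
filter_fold_r <- function(x, q) {
  st <- filter_state_init()
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    r <- biquad_step(st, x[i], q)
    st <- r$state
    y[i] <- r$y
  }
  y
}

# Embed a template into a zero trace with its peak at sample k (0-based).
place_template <- function(n, tpl, k) {
  x <- numeric(n)
  a <- k - tpl$peak_index
  idx <- a + seq_along(tpl$samples) - 1L
  keep <- idx >= 0 & idx < n
  x[idx[keep] + 1L] <- tpl$samples[keep]
  x
}
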