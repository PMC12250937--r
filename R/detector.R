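#' Detector configuration
#'
#' The hard-threshold rule works in the integer (ADC count) domain: the
#' microvolt threshold is converted once via the LSB scale, and the
#' refractory period once to samples. The filter has unity passband
#' gain, so filtered counts and the converted threshold share a scale.
#'
#' @param threshold_uV detection threshold in microvolts (< 0).
#' @param refractory_ms refractory period in milliseconds (> 0);
#'   default 1.5 ms.
#' @param fs_hz sampling rate in Hz.
#' @param scale_uV_per_count LSB scale (default [ADC_UV_PER_COUNT]).
#' @return A `detector_config` list with the derived
#'   `threshold_counts = round(threshold_uV / scale)` and
#'   `refractory_samples = round(refractory_ms * fs_hz / 1000)`.
#' @export
detector_config <- function(threshold_uV, refractory_ms = 1.5, fs_hz,
                            scale_uV_per_count = ADC_UV_PER_COUNT) {
  if (threshold_uV >= 0) stop("threshold_uV must be negative")
  if (refractory_ms <= 0) stop("refractory_ms must be positive")
  rs <- as.integer(round(refractory_ms * fs_hz / 1000))
  if (rs < 1) stop("refractory shorter than one sample")
  structure(list(threshold_uV = threshold_uV, refractory_ms = refractory_ms,
                 fs_hz = as.integer(fs_hz),
                 threshold_counts = as.integer(round(threshold_uV /
                                                       scale_uV_per_count)),
                 refractory_samples = rs),
            class = "detector_config")
}

#' Initial per-channel detector state
#'
#' @return List with the two previous filtered samples `y1` (t-1) and
#'   `y2` (t-2), the `refractory` counter and `samples_seen`.
#' @export
detector_state_init <- function() {
  list(y1 = 0L, y2 = 0L, refractory = 0L, samples_seen = 0)
}

#' One step of the three-sample peak detector (reference implementation)
#'
#' A spike is declared at the sample `t-1` when (i) it is the lowest of
#' the samples at `t-2`, `t-1`, `t` and (ii) it lies strictly below the
#' threshold — evaluated as `y1 < y_t`, `y1 <= y2` and
#' `y1 < threshold_counts`, so a flat-bottomed trough fires once, at its
#' last minimum sample. At least two samples must have been seen. While
#' the per-channel refractory counter is active the conditions are not
#' evaluated at all and the counter decreases by one per call (one call
#' per acquisition loop); a detection arms it to `refractory_samples`.
#'
#' @param state a [detector_state_init()] list.
#' @param y_t current filtered sample in counts.
#' @param cfg a [detector_config()].
#' @return List with `state` (updated) and `spike` (logical; if `TRUE`
#'   the event's peak is the previous sample, ordinal
#'   `state$samples_seen - 2` after the update).
#' @export
detect_step <- function(state, y_t, cfg) {
  spike <- FALSE
  if (state$refractory > 0) {
    state$refractory <- state$refractory - 1L
  } else if (state$samples_seen >= 2 && state$y1 < y_t &&
             state$y1 <= state$y2 && state$y1 < cfg$threshold_counts) {
    spike <- TRUE
    state$refractory <- cfg$refractory_samples
  }
  state$y2 <- state$y1
  state$y1 <- as.integer(y_t)
  state$samples_seen <- state$samples_seen + 1
  list(state = state, spike = spike)
}

#' Offline spike detection on a stored filtered trace
#'
#' Exactly the left-fold of [detect_step()] from a fresh state: the
#' batch reference is definitionally the same automaton the streaming
#' engine runs, which is what makes streaming-vs-offline comparisons
#' exact.
#'
#' @param filtered integer vector of filtered samples in counts.
#' @param cfg a [detector_config()].
#' @param state optional carried state (chunked use).
#' @return Numeric vector of 0-based peak sample indices, with the
#'   final state attached as attribute `state`.
#' @export
detect_offline <- function(filtered, cfg, state = detector_state_init()) {
  r <- cpp_detect_batch(as.integer(filtered), cfg$threshold_counts,
                        cfg$refractory_samples,
                        as.integer(c(state$y1, state$y2, state$refractory)),
                        as.double(state$samples_seen))
  ev <- r$events
  attr(ev, "state") <- list(y1 = r$state[1], y2 = r$state[2],
                            refractory = r$state[3], samples_seen = r$seen)
  ev
}

#' Write spike events to CSV
#'
#' Header `headstage,channel,sample_index,time_s,threshold_uV`;
#' `time_s = sample_index / fs` with 0-based sample indices.
#'
#' @param events data frame with `headstage`, `channel`, `sample_index`.
#' @param fs_hz sampling rate used to derive `time_s`.
#' @param threshold_uV threshold the events were detected at.
#' @param path file path.
#' @export
write_spike_csv <- function(events, fs_hz, threshold_uV, path) {
  out <- data.frame(headstage = events$headstage, channel = events$channel,
                    sample_index = events$sample_index,
                    time_s = events$sample_index / fs_hz,
                    threshold_uV = rep(threshold_uV,
                                       length.out = length(events$sample_index)))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
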