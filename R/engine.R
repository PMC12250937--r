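#' Streaming engine configuration
#'
#' Binds the stream geometry to the datapath: sampling rate and its
#' paired system clock (30 kHz -> 84 MHz, 25 kHz -> 70 MHz,
#' 20 kHz -> 56 MHz; every pair gives 2800 clock cycles per sampling
#' period), the per-channel pipeline depth of the shared
#' filter/detector path, the detector configuration and the quantized
#' filter.
#'
#' @param fs_hz sampling rate, one of 20000, 25000, 30000 Hz.
#' @param detector a [detector_config()] (its `fs_hz` must match).
#' @param filter a [quantize_biquad()] object (its `fs_hz` must match).
#' @param clock_hz system clock; defaults to the pair for `fs_hz` and
#'   must equal it if given.
#' @param pipeline_cycles_per_channel clock cycles the shared datapath
#'   spends per channel per frame (default 20).
#' @return An `engine_config` list.
#' @export
engine_config <- function(fs_hz, detector, filter, clock_hz = NULL,
                          pipeline_cycles_per_channel = 20L) {
  pairs <- c(`20000` = 56e6, `25000` = 70e6, `30000` = 84e6)
  key <- as.character(as.integer(fs_hz))
  if (!key %in% names(pairs))
    stop("fs_hz must be 20000, 25000 or 30000")
  paired <- unname(pairs[key])
  if (is.null(clock_hz)) clock_hz <- paired
  if (clock_hz != paired)
    stop("unsupported (fs_hz, clock_hz) pair; ", key, " Hz pairs with ",
         paired / 1e6, " MHz")
  stopifnot(inherits(detector, "detector_config"),
            inherits(filter, "quantized_biquad"))
  if (detector$fs_hz != as.integer(fs_hz) || filter$fs_hz != as.integer(fs_hz))
    stop("detector/filter were configured for a different sampling rate")
  structure(list(fs_hz = as.integer(fs_hz), clock_hz = clock_hz,
                 pipeline_cycles_per_channel =
                   as.integer(pipeline_cycles_per_channel),
                 detector = detector, filter = filter),
            class = "engine_config")
}

#' Initialize the engine's per-channel state stores
#'
#' All 128 addressable channel slots (8 headstages x 16 channels,
#' addressed `headstage * 16 + channel`) are materialized regardless of
#' how many channels the stream drives — the datapath behaves as if
#' every channel were connected.
#'
#' @return An `engine_state` list: filter states `w1`, `w2`, detector
#'   states `y1`, `y2`, `refractory`, `seen` (each length 128), plus
#'   `carry` (undecoded tail bytes from a previous chunk) and counters.
#' @export
engine_state_init <- function() {
  structure(list(w1 = integer(128), w2 = integer(128),
                 y1 = integer(128), y2 = integer(128),
                 refractory = integer(128), seen = numeric(128),
                 carry = raw(0), frames_done = 0,
                 resync_events = 0L, bytes_skipped = 0),
            class = "engine_state")
}

#' Run the streaming datapath over a framed byte stream
#'
#' Emulates the real-time loop: frames are decoded, and within each
#' frame the channels are visited in serialization order through a
#' single shared filter + detector datapath whose per-channel states
#' are fetched from and written back to the 128-slot state store. The
#' output stream carries the filtered samples in place of the raw ones
#' (payload kind 1) together with the per-channel spike-flag bitmap;
#' detected events carry the 0-based per-channel ordinal of the peak
#' sample, directly comparable with [detect_offline()] indices.
#'
#' Chunked use: pass the returned `state` back in and set
#' `finalize = FALSE` for all but the last chunk; a partial trailing
#' frame is then carried over instead of dropped, and processing a
#' stream in chunks is exactly equivalent to one-shot processing.
#'
#' @param bytes a raw-payload `.nsf` stream (header included unless
#'   `state` carries one from a previous chunk and `header` is given).
#' @param engine an [engine_config()].
#' @param state an [engine_state_init()] carry-over, or `NULL`.
#' @param header optional pre-parsed [stream_header()]; when supplied,
#'   `bytes` holds frames only (chunked use).
#' @param finalize drop-and-count a trailing partial frame (`TRUE`) or
#'   carry it (`FALSE`).
#' @return A list: `bytes_out` (filtered `.nsf` stream; frames only if
#'   `header` was supplied), `events` (data frame `headstage`,
#'   `channel`, `sample_index`), `state` (carry-over), and `stats`
#'   (frames, resyncs, skipped/dropped bytes, saturation counters).
#' @export
process_stream <- function(bytes, engine, state = NULL, header = NULL,
                           finalize = TRUE) {
  stopifnot(inherits(engine, "engine_config"))
  emit_header <- is.null(header)
  if (is.null(header)) {
    header <- read_stream_header(bytes)
    bytes <- bytes[-(1:16)]
  }
  if (header$payload_kind != 0L)
    stop("input stream must carry raw samples (payload kind 0)")
  if (header$fs_hz != engine$fs_hz)
    stop("stream sampling rate does not match engine configuration")
  n_tot <- header$n_headstages * header$n_channels_per_hs
  if (n_tot > 128) stop("stream exceeds the 128-channel capacity")
  if (is.null(state)) state <- engine_state_init()
  stopifnot(inherits(state, "engine_state"))
  if (length(state$carry)) bytes <- c(state$carry, bytes)
  d <- cpp_decode_frames(bytes, 0, header$n_headstages,
                         header$n_channels_per_hs, 0L, !finalize)
  r <- cpp_process_frames(d$samples, header$n_headstages,
                          header$n_channels_per_hs, qvec(engine$filter),
                          engine$detector$threshold_counts,
                          engine$detector$refractory_samples,
                          state$w1, state$w2, state$y1, state$y2,
                          state$refractory, state$seen)
  out_header <- stream_header(header$fs_hz, header$n_headstages,
                              header$n_channels_per_hs, 1L)
  body <- cpp_encode_frames(r$filtered, 1L, r$flags, d$frame_index)
  state$w1 <- r$filter_states$w1
  state$w2 <- r$filter_states$w2
  state$y1 <- r$detector_states$y1
  state$y2 <- r$detector_states$y2
  state$refractory <- r$detector_states$refractory
  state$seen <- r$detector_states$seen
  state$carry <- d$tail
  state$frames_done <- state$frames_done + d$frames_decoded
  state$resync_events <- state$resync_events + d$resync_events
  state$bytes_skipped <- state$bytes_skipped + d$bytes_skipped
  events <- data.frame(headstage = r$event_headstage,
                       channel = r$event_channel,
                       sample_index = r$event_sample_index)
  list(bytes_out = if (emit_header) c(write_stream_header(out_header), body)
                   else body,
       out_header = out_header,
       events = events, state = state,
       stats = list(frames = d$frames_decoded,
                    resync_events = d$resync_events,
                    bytes_skipped = d$bytes_skipped,
                    trailing_bytes_dropped = d$trailing_bytes_dropped,
                    n_state_saturated = r$n_state_saturated,
                    n_output_saturated = r$n_output_saturated))
}

#' Spike-detection latency model
#'
#' Worst-case time from a spike's peak arriving at the input to its
#' detection: the three-sample rule needs the two samples that follow
#' the peak (`samples_needed = 2`, set by the 2nd-order filter + peak
#' comparison), plus the serial pipeline's processing time at the
#' paired clock.
#'
#' @param engine an [engine_config()].
#' @param samples_needed samples to acquire before the decision
#'   (default 2).
#' @return A `latency_report` list: `samples_needed`,
#'   `acquisition_time_s`, `processing_time_s`, `total_s`, `total_us`.
#' @examples
#' cfg <- engine_config(20000,
#'   detector_config(-50, 1.5, 20000),
#'   quantize_biquad(design_highpass_butterworth(20000, 300)))
#' latency_model(cfg)$total_us  # 100.357...
#' @export
latency_model <- function(engine, samples_needed = 2L) {
  stopifnot(inherits(engine, "engine_config"))
  acq <- samples_needed / engine$fs_hz
  proc <- engine$pipeline_cycles_per_channel / engine$clock_hz
  structure(list(samples_needed = as.integer(samples_needed),
                 acquisition_time_s = acq, processing_time_s = proc,
                 total_s = acq + proc, total_us = (acq + proc) * 1e6),
            class = "latency_report")
}

#' Per-frame clock-cycle budget
#'
#' One sampling period offers `clock_hz / fs_hz` clock cycles (2800 for
#' every supported pair) in which the shared datapath must serially
#' serve all channels; a channel count is feasible when
#' `n_channels * pipeline_cycles_per_channel` fits the budget.
#'
#' @param engine an [engine_config()].
#' @param n_channels number of driven channels (1--128).
#' @return List: `cycles_available_per_frame`, `cycles_per_channel`
#'   (available budget divided by `n_channels`), `cycles_used`,
#'   `feasible`.
#' @export
cycle_budget <- function(engine, n_channels) {
  stopifnot(inherits(engine, "engine_config"))
  if (n_channels < 1 || n_channels > 128)
    stop("n_channels must lie in [1, 128]")
  avail <- as.integer(round(engine$clock_hz / engine$fs_hz))
  used <- n_channels * engine$pipeline_cycles_per_channel
  list(cycles_available_per_frame = avail,
       cycles_per_channel = avail / n_channels,
       cycles_used = as.integer(used),
       feasible = used <= avail)
}
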