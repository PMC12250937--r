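#' Build a stereotyped action-potential template
#'
#' Templates are negative-going waveforms (extracellular action
#' potentials seen near the soma) sampled at the recording rate. Two
#' stereotypes are provided: `"biphasic"`, a sharp negative deflection
#' followed by a smaller positive rebound (difference of two Gaussians),
#' and `"triangular"`, a piecewise-linear trough, useful for exact
#' hand-computable tests. The waveform's single global minimum equals
#' `peak_amplitude_uV` exactly and its position (`peak_index`, 0-based)
#' is the alignment point used by the ground truth.
#'
#' @param kind `"biphasic"` or `"triangular"`.
#' @param duration_ms template duration in milliseconds, in `[0.5, 3]`.
#' @param peak_amplitude_uV peak amplitude in microvolts; must be negative.
#' @param fs_hz sampling rate in Hz.
#' @return An object of class `spike_template`: a list with `samples`
#'   (microvolts), `duration_ms`, `peak_amplitude_uV`, `peak_index`
#'   (0-based), `fs_hz` and `kind`.
#' @examples
#' tpl <- make_template("biphasic", 1.0, -100, 20000)
#' length(tpl$samples)  # 20 samples
#' min(tpl$samples)     # exactly -100
#' @export
make_template <- function(kind = c("biphasic", "triangular"),
                          duration_ms, peak_amplitude_uV, fs_hz) {
  kind <- match.arg(kind)
  if (!is.numeric(peak_amplitude_uV) || peak_amplitude_uV >= 0)
    stop("peak_amplitude_uV must be negative")
  if (duration_ms < 0.5 || duration_ms > 3)
    stop("duration_ms must lie in [0.5, 3]")
  n <- as.integer(round(duration_ms * fs_hz / 1000))
  if (n < 3) stop("template too short: needs at least 3 samples")
  t <- seq(0, 1, length.out = n)
  if (kind == "biphasic") {
    # Negative lobe centered at 30% of the duration, rebound at 65%;
    # tails decay to < 0.3% of the peak so the ends sit near zero.
    shape <- -exp(-(t - 0.30)^2 / (2 * 0.08^2)) +
      0.30 * exp(-(t - 0.65)^2 / (2 * 0.10^2))
  } else {
    pk <- n %/% 2
    shape <- c(-(0:pk) / pk, -((n - 2 - pk):0) / (n - 1 - pk))
  }
  pk <- which.min(shape)[1L]
  m <- shape[pk]
  tie <- which(shape == m)
  if (length(tie) > 1)  # deterministic tie-break: keep the earliest sample
    shape[setdiff(tie, pk)] <- m * (1 - 1e-9)
  samples <- shape * (peak_amplitude_uV / m)
  structure(list(samples = samples, duration_ms = duration_ms,
                 peak_amplitude_uV = peak_amplitude_uV,
                 peak_index = pk - 1L, fs_hz = as.integer(fs_hz),
                 kind = kind),
            class = "spike_template")
}

#' Draw a spike train with dead time
#'
#' Event times follow a renewal process whose inter-event interval is a
#' fixed dead time plus an exponential gap (a Poisson process with dead
#' time), a standard minimal model of spontaneous single-unit firing.
#' The dead time must be at least 2 ms so that generated trains can never
#' interact with the detector's 1.5 ms refractory window. The expected
#' event count is `rate_hz * duration_s / (1 + rate_hz * refractory_s)`.
#'
#' Uses the current R random number generator stream; seed beforehand for
#' reproducibility.
#'
#' @param rate_hz underlying Poisson intensity in Hz (>= 0).
#' @param duration_s recording duration in seconds.
#' @param refractory_s generator dead time in seconds (>= 0.002).
#' @param fs_hz sampling rate in Hz.
#' @return Sorted integer vector of 0-based spike sample indices; all
#'   inter-spike intervals exceed `refractory_s * fs_hz` samples.
#' @export
generate_spike_train <- function(rate_hz, duration_s, refractory_s = 0.002,
                                 fs_hz = 20000) {
  if (!is.numeric(rate_hz) || rate_hz < 0) stop("rate_hz must be >= 0")
  if (refractory_s < 0.002)
    stop("generator dead time must be >= 2 ms")
  if (rate_hz == 0) return(integer(0))
  n_total <- as.integer(round(duration_s * fs_hz))
  dead_n <- as.integer(round(refractory_s * fs_hz))
  idx <- integer(0)
  pos <- 0
  repeat {
    need <- max(16L, ceiling((n_total - pos) / fs_hz * rate_hz * 1.5) + 16L)
    gaps <- dead_n + ceiling(rexp(need, rate_hz) * fs_hz)
    new <- pos + cumsum(gaps)
    idx <- c(idx, new[new < n_total])
    pos <- new[length(new)]
    if (pos >= n_total) break
  }
  as.integer(idx)
}

#' Per-channel generation parameters
#'
#' @param firing_rate_hz mean firing rate in Hz (>= 0).
#' @param template a [make_template()] object.
#' @param noise_sigma_uV standard deviation of the white Gaussian
#'   background noise, microvolts.
#' @param drift_amplitude_uV amplitude of the low-frequency baseline
#'   sinusoid, microvolts.
#' @param drift_freq_hz drift frequency in Hz; must stay well below the
#'   highpass cutoff so filtering removes it (default 1 Hz).
#' @return A `channel_spec` list.
#' @export
channel_spec <- function(firing_rate_hz, template, noise_sigma_uV = 15,
                         drift_amplitude_uV = 0, drift_freq_hz = 1) {
  stopifnot(inherits(template, "spike_template"),
            firing_rate_hz >= 0, noise_sigma_uV >= 0,
            drift_amplitude_uV >= 0, drift_freq_hz >= 0)
  if (drift_amplitude_uV > 0 && drift_freq_hz >= 10)
    stop("drift_freq_hz must be < 10 Hz so the highpass removes it")
  structure(list(firing_rate_hz = firing_rate_hz, template = template,
                 noise_sigma_uV = noise_sigma_uV,
                 drift_amplitude_uV = drift_amplitude_uV,
                 drift_freq_hz = drift_freq_hz),
            class = "channel_spec")
}

#' Describe a synthetic multi-channel recording
#'
#' @param fs_hz sampling rate, one of 20000, 25000, 30000 Hz.
#' @param duration_s duration in seconds (> 0).
#' @param n_headstages number of headstages (1--8).
#' @param n_channels_per_hs channels per headstage (1--16).
#' @param channel_specs named list of [channel_spec()] objects keyed
#'   `"h<hs>c<ch>"` with 0-based indices; channels without an entry stay
#'   silent (zero trace).
#' @param seed master seed; every channel derives its own substream.
#' @param dead_time_s generator dead time between spikes on a channel,
#'   seconds (default 0.002; must exceed the detector refractory).
#' @return A `recording_spec` list.
#' @export
recording_spec <- function(fs_hz, duration_s, n_headstages,
                           n_channels_per_hs, channel_specs, seed,
                           dead_time_s = 0.002) {
  if (!fs_hz %in% c(20000L, 25000L, 30000L))
    stop("fs_hz must be 20000, 25000 or 30000")
  stopifnot(duration_s > 0, n_headstages >= 1, n_headstages <= 8,
            n_channels_per_hs >= 1, n_channels_per_hs <= 16)
  if (n_headstages * n_channels_per_hs > 128)
    stop("at most 128 channels")
  labs <- serial_order(n_headstages, n_channels_per_hs)$label
  if (!all(names(channel_specs) %in% labs))
    stop("channel_specs keys must be among: ", paste(labs, collapse = ", "))
  structure(list(fs_hz = as.integer(fs_hz), duration_s = duration_s,
                 n_headstages = as.integer(n_headstages),
                 n_channels_per_hs = as.integer(n_channels_per_hs),
                 channel_specs = channel_specs, seed = as.integer(seed),
                 dead_time_s = dead_time_s),
            class = "recording_spec")
}

# Documented counter scheme for per-channel RNG substreams: channel
# (hs, ch) uses seed master + 1000003 * (hs*16 + ch + 1), reduced mod
# 2^31 - 1.  Adding or removing other channels never perturbs a
# channel's stream.
channel_seed <- function(master_seed, hs, ch) {
  (as.double(master_seed) + 1000003 * (hs * 16 + ch + 1)) %% 2147483647
}

#' Generate a synthetic multi-channel recording with ground truth
#'
#' Each channel's trace (in microvolts) is white Gaussian noise plus a
#' low-frequency drift sinusoid (random phase) plus action-potential
#' templates added at spike times drawn by [generate_spike_train()]. The
#' template's peak sample is aligned to the ground-truth index; a
#' template running past the end of the trace is truncated at the
#' boundary. Channels use independent RNG substreams derived from the
#' master seed by a fixed counter scheme, so results are reproducible
#' and unaffected by which other channels are configured.
#'
#' @param spec a [recording_spec()].
#' @return A list with `traces_uV` (matrix, one column per serialized
#'   channel slot, labelled `"h<hs>c<ch>"`), `ground_truth` (data frame
#'   `headstage`, `channel`, `sample_index`, 0-based, sorted) and `spec`.
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "recording_spec"))
  n <- as.integer(round(spec$duration_s * spec$fs_hz))
  ord <- serial_order(spec$n_headstages, spec$n_channels_per_hs)
  traces <- matrix(0, nrow = n, ncol = nrow(ord),
                   dimnames = list(NULL, ord$label))
  gt <- list()
  for (i in seq_len(nrow(ord))) {
    lab <- ord$label[i]
    cs <- spec$channel_specs[[lab]]
    if (is.null(cs)) next
    hs <- ord$headstage[i]; ch <- ord$channel[i]
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(channel_seed(spec$seed, hs, ch))
    idx <- generate_spike_train(cs$firing_rate_hz, spec$duration_s,
                                spec$dead_time_s, spec$fs_hz)
    phase <- runif(1, 0, 2 * pi)
    x <- if (cs$noise_sigma_uV > 0) rnorm(n, 0, cs$noise_sigma_uV) else numeric(n)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    if (cs$drift_amplitude_uV > 0) {
      tt <- (seq_len(n) - 1) / spec$fs_hz
      x <- x + cs$drift_amplitude_uV * sin(2 * pi * cs$drift_freq_hz * tt + phase)
    }
    tpl <- cs$template$samples
    pk <- cs$template$peak_index
    for (k in idx) {
      a <- k - pk
      b <- a + length(tpl) - 1L
      lo <- max(a, 0L); hi <- min(b, n - 1L)
      if (lo > hi) next
      x[(lo + 1):(hi + 1)] <- x[(lo + 1):(hi + 1)] + tpl[(lo - a + 1):(hi - a + 1)]
    }
    traces[, i] <- x
    if (length(idx))
      gt[[lab]] <- data.frame(headstage = hs, channel = ch, sample_index = idx)
  }
  ground_truth <- if (length(gt)) do.call(rbind, unname(gt)) else
    data.frame(headstage = integer(0), channel = integer(0),
               sample_index = integer(0))
  ground_truth <- ground_truth[order(ground_truth$headstage,
                                     ground_truth$channel,
                                     ground_truth$sample_index), ,
                               drop = FALSE]
  rownames(ground_truth) <- NULL
  list(traces_uV = traces, ground_truth = ground_truth, spec = spec)
}

#' Convert a microvolt trace to 16-bit ADC counts
#'
#' Counts are `round(uV / scale)` saturated to the signed 16-bit range.
#' The inverse scaling `count * scale` recovers the voltage to within
#' half an LSB. Saturation is silent but counted.
#'
#' @param trace_uV numeric vector (or matrix) in microvolts.
#' @param scale_uV_per_count LSB scale (default [ADC_UV_PER_COUNT]).
#' @return Integer vector/matrix of counts with attribute `n_saturated`.
#' @examples
#' to_adc_counts(c(0, -97.5))  # 0, -500
#' @export
to_adc_counts <- function(trace_uV, scale_uV_per_count = ADC_UV_PER_COUNT) {
  cnt <- round(trace_uV / scale_uV_per_count)
  n_sat <- sum(cnt < -32768 | cnt > 32767)
  cnt <- pmin(pmax(cnt, -32768), 32767)
  out <- if (is.matrix(trace_uV))
    matrix(as.integer(cnt), nrow(trace_uV), ncol(trace_uV),
           dimnames = dimnames(trace_uV))
  else as.integer(cnt)
  attr(out, "n_saturated") <- as.integer(n_sat)
  out
}

#' Read and write recording specifications as YAML
#'
#' The YAML layout uses keys `fs_hz`, `duration_s`, `n_headstages`,
#' `n_channels_per_hs`, `seed` and a `channels` list whose entries carry
#' `headstage`, `channel`, `firing_rate_hz`, `noise_sigma_uV`,
#' `drift_amplitude_uV`, `drift_freq_hz` and a `template` block
#' (`kind`, `duration_ms`, `peak_amplitude_uV`).
#'
#' @param spec a [recording_spec()].
#' @param path file path.
#' @return `read_recording_spec_yaml()` returns a `recording_spec`;
#'   `write_recording_spec_yaml()` returns `path` invisibly.
#' @export
write_recording_spec_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "recording_spec"))
  chans <- lapply(names(spec$channel_specs), function(lab) {
    cs <- spec$channel_specs[[lab]]
    m <- regmatches(lab, regexec("^h([0-9]+)c([0-9]+)$", lab))[[1]]
    list(headstage = as.integer(m[2]), channel = as.integer(m[3]),
         firing_rate_hz = cs$firing_rate_hz,
         noise_sigma_uV = cs$noise_sigma_uV,
         drift_amplitude_uV = cs$drift_amplitude_uV,
         drift_freq_hz = cs$drift_freq_hz,
         template = list(kind = cs$template$kind,
                         duration_ms = cs$template$duration_ms,
                         peak_amplitude_uV = cs$template$peak_amplitude_uV))
  })
  yaml::write_yaml(list(fs_hz = spec$fs_hz, duration_s = spec$duration_s,
                        n_headstages = spec$n_headstages,
                        n_channels_per_hs = spec$n_channels_per_hs,
                        seed = spec$seed, dead_time_s = spec$dead_time_s,
                        channels = chans), path)
  invisible(path)
}

#' @rdname write_recording_spec_yaml
#' @export
read_recording_spec_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("fs_hz", "duration_s", "n_headstages", "n_channels_per_hs",
            "seed", "channels")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("missing config keys: ", paste(miss, collapse = ", "))
  specs <- list()
  for (c0 in y$channels) {
    tpl <- make_template(c0$template$kind, c0$template$duration_ms,
                         c0$template$peak_amplitude_uV, y$fs_hz)
    specs[[sprintf("h%dc%d", c0$headstage, c0$channel)]] <-
      channel_spec(c0$firing_rate_hz, tpl, c0$noise_sigma_uV,
                   c0$drift_amplitude_uV,
                   if (is.null(c0$drift_freq_hz)) 1 else c0$drift_freq_hz)
  }
  recording_spec(y$fs_hz, y$duration_s, y$n_headstages,
                 y$n_channels_per_hs, specs, y$seed,
                 if (is.null(y$dead_time_s)) 0.002 else y$dead_time_s)
}

#' Read and write ground-truth spike times as CSV
#'
#' Plain CSV with header `headstage,channel,sample_index` (0-based).
#'
#' @param ground_truth data frame as returned by [generate_recording()].
#' @param path file path.
#' @export
write_ground_truth_csv <- function(ground_truth, path) {
  write.csv(ground_truth[, c("headstage", "channel", "sample_index")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth_csv
#' @export
read_ground_truth_csv <- function(path) {
  read.csv(path, colClasses = c("integer", "integer", "integer"))
}
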