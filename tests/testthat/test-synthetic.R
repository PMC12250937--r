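test_that("templates have the exact requested peak, length and alignment", {
  cases <- expand.grid(kind = c("biphasic", "triangular"),
                       fs = c(20000L, 30000L),
                       amp = c(-50, -100, -300),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    k <- cases$kind[i]; fs <- cases$fs[i]; amp <- cases$amp[i]
    tpl <- make_template(k, 1.0, amp, fs)
    expect_length(tpl$samples, round(1.0 * fs / 1000))
    expect_identical(min(tpl$samples), amp)
    expect_equal(sum(tpl$samples == amp), 1L)          # unique global minimum
    expect_identical(which.min(tpl$samples) - 1L, tpl$peak_index)
    expect_lt(abs(tpl$samples[1]), 1)                  # ends near zero
    expect_lt(abs(tpl$samples[length(tpl$samples)]), 1)
  }
  tri <- make_template("triangular", 1.0, -50, 20000)
  expect_identical(tri$peak_index, length(tri$samples) %/% 2L)  # midpoint
  expect_error(make_template("biphasic", 1.0, 100, 20000), "negative")
  expect_error(make_template("biphasic", 0.2, -100, 20000), "duration")
  # deterministic for fixed arguments
  expect_identical(make_template("biphasic", 1.3, -120, 25000),
                   make_template("biphasic", 1.3, -120, 25000))
})

test_that("spike trains respect the dead time and the corrected rate", {
  expect_identical(generate_spike_train(0, 10), integer(0))
  expect_error(generate_spike_train(-1, 10), ">= 0")
  expect_error(generate_spike_train(5, 10, refractory_s = 0.001), "2 ms")
  # every inter-spike interval exceeds the dead time, across seeds
  for (s in 1:20) {
    set.seed(s)
    idx <- generate_spike_train(30, 5, 0.002, 20000)
    expect_true(all(diff(idx) >= 0.002 * 20000))
    expect_true(all(idx >= 0 & idx < 5 * 20000))
  }
  # Monte-Carlo mean against the dead-time-corrected closed form
  cnt <- vapply(1:200, function(s) {
    set.seed(s)
    length(generate_spike_train(5, 60, 0.002, 20000))
  }, numeric(1))
  expected <- 5 * 60 / (1 + 5 * 0.002)
  se <- sd(cnt) / sqrt(length(cnt))
  expect_lt(abs(mean(cnt) - expected), 3 * se)
})

test_that("ADC conversion rounds, saturates and inverts within half an LSB", {
  expect_identical(to_adc_counts(0)[1], 0L)
  expect_identical(to_adc_counts(-97.5)[1], -500L)   # -97.5 / 0.195 exactly
  sat <- to_adc_counts(-10000)
  expect_identical(sat[1], -32768L)
  expect_identical(attr(sat, "n_saturated"), 1L)
  uv <- runif(1000, -6000, 6000)
  cnt <- to_adc_counts(uv)
  expect_identical(attr(cnt, "n_saturated"), 0L)
  expect_true(all(abs(cnt * 0.195 - uv) <= 0.0975 + 1e-12))
})

test_that("recordings are deterministic with per-channel substreams", {
  tpl <- make_template("biphasic", 1.0, -150, 20000)
  silent <- recording_spec(20000, 0.2, 1, 2,
                           list(h0c0 = channel_spec(0, tpl, 0, 0)), seed = 1)
  rec0 <- generate_recording(silent)
  expect_true(all(rec0$traces_uV == 0))
  expect_identical(nrow(rec0$ground_truth), 0L)

  noiseless <- recording_spec(20000, 2, 1, 1,
                              list(h0c0 = channel_spec(5, tpl, 0, 0)),
                              seed = 11)
  rec1 <- generate_recording(noiseless)
  expect_gt(nrow(rec1$ground_truth), 0)
  expect_equal(min(rec1$traces_uV), -150)  # noiseless, non-overlapping peaks
  gt <- rec1$ground_truth$sample_index
  expect_true(all(diff(gt) >= 0.002 * 20000))
  expect_true(all(rec1$traces_uV[gt + 1] == -150))  # peak aligned to index

  rec2 <- generate_recording(noiseless)
  expect_identical(rec1$traces_uV, rec2$traces_uV)   # bitwise reproducible
  expect_identical(rec1$ground_truth, rec2$ground_truth)

  # adding channels leaves an existing channel's data untouched
  both <- recording_spec(20000, 2, 1, 2,
                         list(h0c0 = channel_spec(5, tpl, 0, 0),
                              h0c1 = channel_spec(9, tpl, 12, 150)),
                         seed = 11)
  rec3 <- generate_recording(both)
  expect_identical(rec3$traces_uV[, "h0c0"], rec1$traces_uV[, "h0c0"])
})

test_that("noiseless spikes are detected at the ground-truth index", {
  q <- hp20()
  for (tpl in list(make_template("biphasic", 1.2, -150, 20000),
                   make_template("biphasic", 1.0, -80, 20000),
                   make_template("triangular", 0.6, -200, 20000))) {
    det <- detector_config(0.6 * tpl$peak_amplitude_uV, 1.5, 20000)
    x <- place_template(4000, tpl, 2000)
    ev <- detect_offline(filter_batch(to_adc_counts(x), q), det)
    expect_length(ev, 1)
    expect_lte(abs(ev - 2000), 2)  # within the filter group-delay tolerance
  }
})

test_that("slow drift within the linear range is rejected by the highpass", {
  q <- hp20()
  tt <- (0:39999) / 20000
  x <- to_adc_counts(50 * sin(2 * pi * 5 * tt))  # 50 uV at 5 Hz
  y <- filter_batch(x, q)
  expect_identical(attr(y, "n_saturated"), 0)
  expect_true(all(y > -50 / 0.195))  # never crosses -50 uV
  expect_lt(max(abs(y)), 3)          # residual is a couple of counts
})

test_that("drift beyond the state headroom saturates boundedly and is counted", {
  q <- hp20()
  tt <- (0:39999) / 20000
  x <- to_adc_counts(500 * sin(2 * pi * 5 * tt))
  y <- filter_batch(x, q)
  expect_gt(attr(y, "n_saturated"), 0)     # 32-bit state store clips
  expect_true(all(is.finite(y)))
  expect_lt(max(abs(y)), 2^15)             # output stays in sample range
  # saturation is part of the datapath: streaming equals offline exactly
  h <- stream_header(20000, 1, 1, 0)
  eng <- engine_config(20000, detector_config(-50, 1.5, 20000), q)
  res <- process_stream(encode_stream(matrix(x, ncol = 1), h), eng)
  ev <- detect_offline(y, detector_config(-50, 1.5, 20000))
  expect_identical(sort(res$events$sample_index), as.numeric(ev))
})

test_that("recording specs and ground truth survive YAML/CSV round trips", {
  tpl <- make_template("biphasic", 1.2, -120, 20000)
  spec <- recording_spec(20000, 0.5, 2, 3,
                         list(h0c0 = channel_spec(4, tpl, 15, 100, 2),
                              h1c2 = channel_spec(7, tpl, 10, 0)),
                         seed = 99)
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_recording_spec_yaml(spec, yml)
  spec2 <- read_recording_spec_yaml(yml)
  expect_identical(generate_recording(spec)$traces_uV,
                   generate_recording(spec2)$traces_uV)
  expect_error(read_recording_spec_yaml({
    bad <- withr::local_tempfile(fileext = ".yaml")
    yaml::write_yaml(list(fs_hz = 20000), bad); bad
  }), "missing config keys")

  rec <- generate_recording(spec)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth_csv(rec$ground_truth, csv)
  expect_identical(read_ground_truth_csv(csv)$sample_index,
                   rec$ground_truth$sample_index)
  expect_identical(readLines(csv, n = 1), "headstage,channel,sample_index")
})
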