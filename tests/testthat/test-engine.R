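make_engine <- function(fs = 20000, th = -50, cycles = 20L) {
  engine_config(fs, detector_config(th, 1.5, fs),
                quantize_biquad(design_highpass_butterworth(fs, 300)),
                pipeline_cycles_per_channel = cycles)
}

test_that("configuration enforces the supported clock pairings", {
  eng <- make_engine(25000)
  expect_identical(eng$clock_hz, 70e6)
  expect_identical(make_engine(30000)$clock_hz, 84e6)
  expect_error(engine_config(20000, detector_config(-50, 1.5, 20000),
                             hp20(), clock_hz = 84e6), "pair")
  expect_error(engine_config(20000, detector_config(-50, 1.5, 25000),
                             hp20()), "sampling rate")
})

test_that("a single-channel stream reproduces the offline reference", {
  set.seed(301)
  eng <- make_engine()
  h <- stream_header(20000, 1, 1, 0)
  x <- random_spiky_trace(6000, sigma = 120, n_spikes = 12)
  res <- process_stream(encode_stream(matrix(x, ncol = 1), h), eng)
  y <- filter_batch(x, eng$filter)
  ev <- detect_offline(y, eng$detector)
  expect_identical(sort(res$events$sample_index), as.numeric(ev))
  # the output stream carries exactly the batch-filtered samples
  out <- decode_stream(res$bytes_out)
  expect_identical(out$header$payload_kind, 1L)
  expect_identical(as.integer(out$samples[, 1]), as.integer(y))
  # flags are raised in the frame after the peak, on the right channel
  flagged <- which(out$flags[, 1]) - 1L
  expect_identical(sort(as.numeric(flagged)), as.numeric(ev) + 1)
})

test_that("every channel of a multi-channel stream matches its isolated run", {
  set.seed(302)
  n_hs <- 2L; n_ch <- 3L
  eng <- make_engine()
  h <- stream_header(20000, n_hs, n_ch, 0)
  x <- sapply(1:(n_hs * n_ch), function(i)
    random_spiky_trace(3000, sigma = 130, n_spikes = 8))
  res <- process_stream(encode_stream(x, h), eng)
  ord <- serial_order(n_hs, n_ch)
  out <- decode_stream(res$bytes_out)
  for (i in seq_len(nrow(ord))) {
    y <- filter_batch(x[, i], eng$filter)
    ev <- detect_offline(y, eng$detector)
    got <- sort(res$events$sample_index[
      res$events$headstage == ord$headstage[i] &
        res$events$channel == ord$channel[i]])
    expect_identical(got, as.numeric(ev))
    expect_identical(as.integer(out$samples[, i]), as.integer(y))
    # interleaving invariance: identical to a lone-channel stream
    solo <- process_stream(
      encode_stream(x[, i, drop = FALSE], stream_header(20000, 1, 1, 0)),
      eng)
    expect_identical(sort(solo$events$sample_index), got)
  }
})

test_that("a spike on one of 128 channels stays on that channel", {
  eng <- make_engine()
  h <- stream_header(20000, 8, 16, 0)
  tpl <- make_template("biphasic", 1.2, -300, 20000)
  n <- 2000L
  x <- matrix(0L, n, 128)
  ord <- serial_order(8, 16)
  target <- which(ord$headstage == 7 & ord$channel == 15)
  x[, target] <- to_adc_counts(place_template(n, tpl, 1000))
  res <- process_stream(encode_stream(x, h), eng)
  expect_identical(nrow(res$events), 1L)
  expect_identical(res$events$headstage, 7L)
  expect_identical(res$events$channel, 15L)
  expect_identical(res$events$sample_index, 1000)
  expect_identical(res$stats$frames, n)
})

test_that("chunked processing with carried state equals one-shot", {
  set.seed(303)
  eng <- make_engine()
  h <- stream_header(20000, 2, 2, 0)
  x <- sapply(1:4, function(i) random_spiky_trace(1500, n_spikes = 6))
  full <- encode_stream(x, h)
  one <- process_stream(full, eng)
  # split mid-frame, well away from any boundary
  body <- full[-(1:16)]
  cut <- 777
  st <- engine_state_init()
  r1 <- process_stream(body[1:cut], eng, state = st, header = h,
                       finalize = FALSE)
  r2 <- process_stream(body[(cut + 1):length(body)], eng, state = r1$state,
                       header = h, finalize = TRUE)
  expect_identical(rbind(r1$events, r2$events), one$events)
  expect_identical(c(r1$bytes_out, r2$bytes_out), one$bytes_out[-(1:16)])
  expect_identical(r1$state$frames_done + r2$stats$frames,
                   one$stats$frames + 0)
})

test_that("output frame count equals decodable input frame count", {
  set.seed(304)
  eng <- make_engine()
  h <- stream_header(20000, 1, 2, 0)
  b <- encode_stream(random_samples(20, 2), h)
  flen <- 8 + 4 + 4
  cut <- 16 + 7 * flen
  corrupt <- c(b[1:cut], as.raw(c(1, 2, 3, 4, 5)), b[(cut + 1):length(b)])
  res <- process_stream(corrupt, eng)
  expect_identical(res$stats$frames, 20L)
  expect_identical(res$stats$resync_events, 1L)
  out <- decode_stream(res$bytes_out)
  expect_identical(out$state$frames_decoded, 20L)
  expect_identical(out$frame_index, 0:19)
})

test_that("the latency model matches the two-sample acquisition bound", {
  expect_equal(latency_model(make_engine(20000))$total_us,
               2 / 20000 * 1e6 + 20 / 56e6 * 1e6)
  expect_lte(latency_model(make_engine(20000))$total_us, 100.37)
  expect_equal(latency_model(make_engine(25000))$total_us, 80.29,
               tolerance = 1e-4)
  eng0 <- make_engine(20000, cycles = 0L)
  expect_identical(latency_model(eng0)$total_s, 2 / 20000)
})

test_that("the cycle budget is 2800 at every pairing and caps at 128 channels", {
  for (fs in c(20000, 25000, 30000)) {
    bud <- cycle_budget(make_engine(fs), 128)
    expect_identical(bud$cycles_available_per_frame, 2800L)
    expect_true(bud$feasible)                    # 128 x 20 = 2560 <= 2800
    expect_identical(bud$cycles_used, 2560L)
  }
  expect_false(cycle_budget(make_engine(20000, cycles = 22L), 128)$feasible)
  expect_error(cycle_budget(make_engine(), 129), "128")
  expect_error(cycle_budget(make_engine(), 0), "128")
})

test_that("filtered streams are rejected as engine input", {
  eng <- make_engine()
  h <- stream_header(20000, 1, 1, 0)
  res <- process_stream(encode_stream(matrix(0L, 5, 1), h), eng)
  expect_error(process_stream(res$bytes_out, eng), "payload kind 0")
})
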