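#' Design the 2nd-order highpass Butterworth section
#'
#' Closed-form bilinear transform with cutoff prewarping
#' `K = tan(pi * fc / fs)`:
#' `norm = 1 + sqrt(2) K + K^2`, `b = (1, -2, 1) / norm`,
#' `a1 = 2 (K^2 - 1) / norm`, `a2 = (1 - sqrt(2) K + K^2) / norm`
#' (`a0` normalized to 1). The feedforward taps sum to zero, so the DC
#' gain is exactly zero; the magnitude at `fc` is `1/sqrt(2)`.
#'
#' @param fs_hz sampling rate in Hz.
#' @param fc_hz cutoff (-3 dB) frequency in Hz, `0 < fc < fs/2`.
#' @return A `biquad_coeffs` list: `b0, b1, b2, a1, a2, fs_hz, fc_hz`.
#' @examples
#' design_highpass_butterworth(20000, 300)
#' @export
design_highpass_butterworth <- function(fs_hz, fc_hz = 300) {
  if (fc_hz <= 0 || fc_hz >= fs_hz / 2)
    stop("fc_hz must lie strictly between 0 and fs_hz/2")
  K <- tan(pi * fc_hz / fs_hz)
  norm <- 1 + sqrt(2) * K + K^2
  structure(list(b0 = 1 / norm, b1 = -2 / norm, b2 = 1 / norm,
                 a1 = 2 * (K^2 - 1) / norm,
                 a2 = (1 - sqrt(2) * K + K^2) / norm,
                 fs_hz = as.integer(fs_hz), fc_hz = fc_hz),
            class = "biquad_coeffs")
}

#' Quantize biquad coefficients to Q2.16 fixed point
#'
#' Coefficients are rounded to nearest (half away from zero) on a
#' signed 18-bit Q2.16 grid (`q = round(c * 2^16)`), then `qb1` is
#' forced to `-(qb0 + qb2)` so the quantized filter keeps an exact DC
#' zero — without this the rounded taps can leak a slow offset.
#'
#' @param coeffs a [design_highpass_butterworth()] result.
#' @return A `quantized_biquad` list: `qb0, qb1, qb2, qa1, qa2` (Q2.16
#'   integers), `shift = 16`, plus the originating `fs_hz`, `fc_hz` and
#'   real coefficients.
#' @export
quantize_biquad <- function(coeffs) {
  stopifnot(inherits(coeffs, "biquad_coeffs"))
  cs <- unlist(coeffs[c("b0", "b1", "b2", "a1", "a2")])
  if (any(abs(cs) >= 2))
    stop("coefficient magnitude >= 2 overflows Q2.16")
  q <- as.integer(round_half_away(cs * 65536))
  qb1 <- -(q[1] + q[3])
  structure(list(qb0 = q[1], qb1 = qb1, qb2 = q[3], qa1 = q[4], qa2 = q[5],
                 shift = 16L, fs_hz = coeffs$fs_hz, fc_hz = coeffs$fc_hz,
                 coeffs = coeffs),
            class = "quantized_biquad")
}

qvec <- function(q) {
  stopifnot(inherits(q, "quantized_biquad"))
  c(q$qb0, q$qb1, q$qb2, q$qa1, q$qa2)
}

#' Initial (zero) Direct-Form-II state
#'
#' The two delay states of the section, stored per channel. States live
#' at `counts << 16` scale as 32-bit integers and start at zero.
#'
#' @return Integer vector `c(w1 = 0, w2 = 0)`.
#' @export
filter_state_init <- function() c(w1 = 0L, w2 = 0L)

#' One fixed-point Direct-Form-II step (reference implementation)
#'
#' Pure-R rendering of the integer datapath, bit-identical to the
#' compiled batch/stream paths (exact because every intermediate stays
#' below 2^53 in double precision):
#' \preformatted{
#'   w  = sat32( (x << 16) - ((qa1 w1 + qa2 w2) >> 16) )
#'   y  = ((qb0 w + qb1 w1 + qb2 w2) >> 16 + 2^15) >> 16
#' }
#' `>>` is an arithmetic (floor) shift; the final shift rounds to
#' nearest (half toward +inf); saturation clamps to ±(2^31 - 1).
#'
#' @param state integer vector `(w1, w2)` from [filter_state_init()].
#' @param x input sample in ADC counts (int16 range).
#' @param q a [quantize_biquad()] object.
#' @return List with `state` (updated) and `y` (filtered counts).
#' @export
biquad_step <- function(state, x, q) {
  shr16 <- function(v) floor(v / 65536)
  w1 <- as.double(state[[1]]); w2 <- as.double(state[[2]])
  fb <- q$qa1 * w1 + q$qa2 * w2
  w <- x * 65536 - shr16(fb)
  w <- min(max(w, -2147483647), 2147483647)
  ff <- q$qb0 * w + q$qb1 * w1 + q$qb2 * w2
  y <- floor((shr16(ff) + 32768) / 65536)
  list(state = c(w1 = as.integer(w), w2 = as.integer(w1)), y = y)
}

#' Filter a whole trace through the fixed-point section
#'
#' Exactly the left-fold of [biquad_step()] from the given state; the
#' compiled loop is bit-identical to the per-channel arithmetic of the
#' streaming engine, which is what makes the offline reference an exact
#' oracle for it.
#'
#' @param x integer vector of samples in ADC counts.
#' @param q a [quantize_biquad()] object.
#' @param state starting state (default zero).
#' @return Integer vector of filtered counts, with attributes `state`
#'   (final state) and `n_saturated`.
#' @export
filter_batch <- function(x, q, state = filter_state_init()) {
  r <- cpp_filter_batch(as.integer(x), qvec(q), as.integer(state))
  out <- r$y
  attr(out, "state") <- c(w1 = r$state[1], w2 = r$state[2])
  attr(out, "n_saturated") <- r$n_saturated
  out
}

#' Magnitude response of a biquad
#'
#' Evaluates `|H(e^{i 2 pi f / fs})|` analytically from either the real
#' or the quantized (rescaled by `2^-16`) coefficients.
#'
#' @param q a `biquad_coeffs` or `quantized_biquad`.
#' @param f_hz frequencies in Hz.
#' @return Numeric vector of magnitudes.
#' @export
biquad_response <- function(q, f_hz) {
  if (inherits(q, "quantized_biquad")) {
    b <- c(q$qb0, q$qb1, q$qb2) / 65536
    a <- c(1, q$qa1, q$qa2) / c(1, 65536, 65536)
    fs <- q$fs_hz
  } else {
    stopifnot(inherits(q, "biquad_coeffs"))
    b <- c(q$b0, q$b1, q$b2)
    a <- c(1, q$a1, q$a2)
    fs <- q$fs_hz
  }
  vapply(f_hz, function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    Mod((b[1] + b[2] * z + b[3] * z^2) / (a[1] + a[2] * z + a[3] * z^2))
  }, numeric(1))
}

#' Locate the -3 dB frequency by bisection
#'
#' Finds the frequency where the (quantized) filter's magnitude crosses
#' `1/sqrt(2)`, bisecting between DC and Nyquist on the numerically
#' evaluated response.
#'
#' @param q a `biquad_coeffs` or `quantized_biquad`.
#' @param tol_hz bisection stopping width in Hz (default 1e-4).
#' @return The -3 dB frequency in Hz.
#' @export
measure_cutoff <- function(q, tol_hz = 1e-4) {
  fs <- q$fs_hz
  target <- 1 / sqrt(2)
  lo <- 1e-6
  hi <- fs / 2 - 1e-6
  if (biquad_response(q, lo) > target || biquad_response(q, hi) < target)
    stop("response does not bracket -3 dB between DC and Nyquist")
  while (hi - lo > tol_hz) {
    mid <- (lo + hi) / 2
    if (biquad_response(q, mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Export and import filter coefficients as JSON
#'
#' Serializes designed and quantized coefficients (`b0..a2`,
#' `qb0..qa2`, `shift`, `fs_hz`, `fc_hz`) for inspection or
#' cross-implementation testing.
#'
#' @param q a [quantize_biquad()] object.
#' @param path file path.
#' @export
write_biquad_json <- function(q, path) {
  stopifnot(inherits(q, "quantized_biquad"))
  co <- q$coeffs
  jsonlite::write_json(
    list(b0 = co$b0, b1 = co$b1, b2 = co$b2, a1 = co$a1, a2 = co$a2,
         qb0 = q$qb0, qb1 = q$qb1, qb2 = q$qb2, qa1 = q$qa1, qa2 = q$qa2,
         shift = q$shift, fs_hz = q$fs_hz, fc_hz = q$fc_hz),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_biquad_json
#' @export
read_biquad_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- structure(list(b0 = j$b0, b1 = j$b1, b2 = j$b2, a1 = j$a1,
                       a2 = j$a2, fs_hz = as.integer(j$fs_hz),
                       fc_hz = j$fc_hz),
                  class = "biquad_coeffs")
  structure(list(qb0 = as.integer(j$qb0), qb1 = as.integer(j$qb1),
                 qb2 = as.integer(j$qb2), qa1 = as.integer(j$qa1),
                 qa2 = as.integer(j$qa2), shift = as.integer(j$shift),
                 fs_hz = as.integer(j$fs_hz), fc_hz = j$fc_hz,
                 coeffs = co),
            class = "quantized_biquad")
}
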