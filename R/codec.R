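#' Stream header
#'
#' The 16-byte header of an `.nsf` container: magic tag `"NSF1"`,
#' version (u16, = 1), sampling rate (u32), headstage count (u8),
#' channels per headstage (u8), payload kind (u8; 0 = raw samples,
#' 1 = filtered samples + spike-flag bitmap) and 3 reserved zero bytes.
#' All multi-byte fields are little-endian.
#'
#' @param fs_hz sampling rate in Hz.
#' @param n_headstages headstages (1--8).
#' @param n_channels_per_hs channels per headstage (1--16).
#' @param payload_kind 0 (raw) or 1 (filtered + flags).
#' @return A `stream_header` list.
#' @export
stream_header <- function(fs_hz, n_headstages, n_channels_per_hs,
                          payload_kind = 0L) {
  stopifnot(n_headstages >= 1, n_headstages <= 8,
            n_channels_per_hs >= 1, n_channels_per_hs <= 16)
  if (!payload_kind %in% c(0L, 1L)) stop("payload_kind must be 0 or 1")
  structure(list(magic = "NSF1", version = 1L, fs_hz = as.integer(fs_hz),
                 n_headstages = as.integer(n_headstages),
                 n_channels_per_hs = as.integer(n_channels_per_hs),
                 payload_kind = as.integer(payload_kind)),
            class = "stream_header")
}

#' @rdname stream_header
#' @param header a `stream_header`.
#' @return `write_stream_header()` returns the 16 header bytes as a raw
#'   vector; `read_stream_header()` parses them back.
#' @export
write_stream_header <- function(header) {
  stopifnot(inherits(header, "stream_header"))
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(charToRaw("NSF1"), con)
  writeBin(header$version, con, size = 2, endian = "little")
  writeBin(header$fs_hz, con, size = 4, endian = "little")
  writeBin(as.integer(header$n_headstages), con, size = 1)
  writeBin(as.integer(header$n_channels_per_hs), con, size = 1)
  writeBin(as.integer(header$payload_kind), con, size = 1)
  writeBin(as.raw(c(0, 0, 0)), con)
  rawConnectionValue(con)
}

#' @rdname stream_header
#' @param bytes raw vector starting with a header.
#' @export
read_stream_header <- function(bytes) {
  if (length(bytes) < 16) stop("stream shorter than a 16-byte header")
  if (rawToChar(bytes[1:4]) != "NSF1") stop("bad magic tag: not an .nsf stream")
  version <- readBin(bytes[5:6], "integer", size = 2, endian = "little",
                     signed = FALSE)
  fs_hz <- readBin(bytes[7:10], "integer", size = 4, endian = "little")
  n_hs <- as.integer(bytes[11])
  n_ch <- as.integer(bytes[12])
  pk <- as.integer(bytes[13])
  if (version != 1L) stop("unsupported stream version: ", version)
  h <- stream_header(fs_hz, n_hs, n_ch, pk)
  h
}

#' Encode a multi-channel recording as a framed byte stream
#'
#' Produces `header || frame_0 || frame_1 || ...`, one frame per
#' sampling period. Each frame is the 8-byte sync word, a 4-byte frame
#' index, the samples of all channels as little-endian int16 in
#' serialization order (see [serial_order()]) and, for payload kind 1,
#' a spike-flag bitmap of `ceiling(n_channels / 8)` bytes (bit `k` of
#' byte `j` flags serialized position `8 j + k`).
#'
#' @param samples integer matrix, one row per frame, one column per
#'   serialized channel position; values in the signed 16-bit range.
#' @param header a [stream_header()]; channel counts must match.
#' @param flags optional logical matrix of spike flags (payload kind 1).
#' @param frame_index0 index of the first frame (default 0).
#' @return Raw vector: the full `.nsf` byte stream.
#' @export
encode_stream <- function(samples, header, flags = NULL, frame_index0 = 0L) {
  stopifnot(inherits(header, "stream_header"))
  if (is.list(samples)) {
    len <- unique(vapply(samples, length, 1L))
    if (length(len) != 1) stop("ragged channel lengths")
    samples <- do.call(cbind, samples)
  }
  ntot <- header$n_headstages * header$n_channels_per_hs
  if (ncol(samples) != ntot)
    stop("channel count does not match header")
  storage.mode(samples) <- "integer"
  fidx <- as.integer(frame_index0 + seq_len(nrow(samples)) - 1L)
  body <- cpp_encode_frames(samples, header$payload_kind, flags, fidx)
  c(write_stream_header(header), body)
}

#' Decode a framed byte stream
#'
#' The byte-level counterpart of folding [fsm_step()] over the 16-bit
#' word stream. While synchronized, frame boundaries are trusted (a
#' sample that happens to equal a sync fragment cannot cause a false
#' resync). On a sync mismatch at an expected boundary the decoder
#' enters `SEEK_SYNC`, scans byte-by-byte for the next sync word,
#' counts one resynchronization event, and resumes; skipped bytes are
#' counted and never emitted as samples. A trailing partial frame is
#' dropped and counted (or carried, see `keep_tail`).
#'
#' @param bytes raw vector; a full `.nsf` stream unless `header` is
#'   supplied, in which case `bytes` holds frames only.
#' @param header optional [stream_header()] already parsed.
#' @param keep_tail if `TRUE`, return undecoded trailing bytes instead
#'   of dropping them (used for chunked streaming).
#' @return A list: `samples` (integer matrix, decoded frames x
#'   serialized channels, labelled), `frame_index`, `flags` (payload
#'   kind 1 only), `header`, `tail`, and `state` — the final decoder
#'   state (`phase`, `frames_decoded`, `resync_events`, `bytes_skipped`,
#'   `trailing_bytes_dropped`).
#' @export
decode_stream <- function(bytes, header = NULL, keep_tail = FALSE) {
  offset <- 0
  if (is.null(header)) {
    header <- read_stream_header(bytes)
    offset <- 16
  }
  ntot <- header$n_headstages * header$n_channels_per_hs
  d <- cpp_decode_frames(bytes, offset, header$n_headstages,
                         header$n_channels_per_hs, header$payload_kind,
                         keep_tail)
  labs <- serial_order(header$n_headstages, header$n_channels_per_hs)$label
  colnames(d$samples) <- labs
  if (header$payload_kind == 1 && ncol(d$flags) == ntot)
    colnames(d$flags) <- labs
  list(samples = d$samples, frame_index = d$frame_index,
       flags = if (header$payload_kind == 1) d$flags else NULL,
       header = header, tail = d$tail,
       state = list(phase = if (d$frames_decoded > 0 &&
                                d$trailing_bytes_dropped == 0 &&
                                length(d$tail) == 0) "IN_FRAME" else "SEEK_SYNC",
                    frames_decoded = d$frames_decoded,
                    resync_events = d$resync_events,
                    bytes_skipped = d$bytes_skipped,
                    trailing_bytes_dropped = d$trailing_bytes_dropped))
}

#' Decoded samples as a tidy table
#'
#' Flattens a [decode_stream()] result into the serialization-order
#' sequence of `(frame_index, headstage, channel, sample)` tuples.
#'
#' @param decoded result of [decode_stream()].
#' @return A data frame in stream order.
#' @export
decoded_tuples <- function(decoded) {
  h <- decoded$header
  ord <- serial_order(h$n_headstages, h$n_channels_per_hs)
  n <- nrow(decoded$samples)
  if (n == 0)
    return(data.frame(frame_index = integer(0), headstage = integer(0),
                      channel = integer(0), sample = integer(0)))
  data.frame(frame_index = rep(decoded$frame_index, each = nrow(ord)),
             headstage = rep(ord$headstage, n),
             channel = rep(ord$channel, n),
             sample = as.vector(t(decoded$samples)))
}

#' Initialize the word-level decoder state machine
#'
#' @param n_headstages,n_channels_per_hs stream geometry.
#' @return A `decoder_state` list: `phase` (`"SEEK_SYNC"` or
#'   `"IN_FRAME"`), `word_position` (words matched/consumed within the
#'   current frame), `current_headstage`, `current_channel`,
#'   `frame_index`, `frames_decoded`, `resync_events`, and `emit` — the
#'   tuple produced by the transition into the current state (`NULL`
#'   when the state emits nothing), making the machine a Moore
#'   automaton: output is a function of the post-transition state only.
#' @export
fsm_init <- function(n_headstages, n_channels_per_hs) {
  structure(list(phase = "SEEK_SYNC", word_position = 0L,
                 current_headstage = 0L, current_channel = 0L,
                 frame_index = NA_integer_, frames_decoded = 0L,
                 resync_events = 0L,
                 n_headstages = as.integer(n_headstages),
                 n_channels_per_hs = as.integer(n_channels_per_hs),
                 emit = NULL),
            class = "decoder_state")
}

#' One transition of the word-level Moore decoder
#'
#' Pure transition function over unsigned 16-bit words of a raw
#' (payload kind 0) stream; [decode_stream()] on a well-formed stream
#' equals the left-fold of `fsm_step` over its word sequence (the sync
#' word is consumed as four 16-bit words, the frame index as two).
#'
#' @param state a `decoder_state` from [fsm_init()] or a previous step.
#' @param word next 16-bit word, as an unsigned integer 0..65535.
#' @return The updated state; `state$emit` holds the emitted
#'   `(frame_index, headstage, channel, sample)` tuple or `NULL`.
#' @export
fsm_step <- function(state, word) {
  stopifnot(inherits(state, "decoder_state"))
  word <- as.integer(word)
  sync <- nsf_sync_words()
  ntot_words <- 4L + 2L + state$n_headstages * state$n_channels_per_hs
  state$emit <- NULL
  if (state$phase == "SEEK_SYNC") {
    expected <- sync[state$word_position + 1L]
    if (word == expected) {
      state$word_position <- state$word_position + 1L
      if (state$word_position == 4L) {
        state$phase <- "IN_FRAME"
      }
    } else {
      # restart the match; allow the mismatching word to begin a new sync
      state$word_position <- if (word == sync[1]) 1L else 0L
    }
    return(state)
  }
  # IN_FRAME: word_position counts words consumed since the sync word
  wp <- state$word_position - 4L
  if (wp == 0L) {            # frame index, low half
    state$frame_index <- word
    state$word_position <- state$word_position + 1L
  } else if (wp == 1L) {     # frame index, high half
    state$frame_index <- state$frame_index + word * 65536
    state$word_position <- state$word_position + 1L
  } else {                   # sample words, serialization order
    s <- wp - 2L
    hs <- s %% state$n_headstages
    ch <- s %/% state$n_headstages
    val <- if (word >= 32768L) word - 65536L else word
    state$emit <- list(frame_index = state$frame_index, headstage = hs,
                       channel = ch, sample = val)
    state$current_headstage <- hs
    state$current_channel <- ch
    state$word_position <- state$word_position + 1L
    if (state$word_position == ntot_words) {
      state$frames_decoded <- state$frames_decoded + 1L
      state$phase <- "SEEK_SYNC"
      state$word_position <- 0L
    }
  }
  state
}

#' Fold the word-level FSM over a raw byte stream
#'
#' Reference decoder used to cross-check [decode_stream()]: converts
#' the frame bytes to little-endian 16-bit words and left-folds
#' [fsm_step()].
#'
#' @param bytes full `.nsf` stream (payload kind 0).
#' @return A data frame of emitted tuples plus the final state as
#'   attribute `"state"`.
#' @export
fsm_decode <- function(bytes) {
  header <- read_stream_header(bytes)
  if (header$payload_kind != 0L)
    stop("word-level FSM is defined for raw (payload kind 0) streams")
  body <- bytes[-(1:16)]
  if (length(body) %% 2 == 1) body <- body[-length(body)]
  words <- readBin(body, "integer", n = length(body) / 2, size = 2,
                   endian = "little", signed = FALSE)
  st <- fsm_init(header$n_headstages, header$n_channels_per_hs)
  out <- vector("list", length(words))
  k <- 0L
  for (w in words) {
    st <- fsm_step(st, w)
    if (!is.null(st$emit)) {
      k <- k + 1L
      out[[k]] <- st$emit
    }
  }
  tuples <- if (k > 0) {
    do.call(rbind, lapply(out[seq_len(k)], as.data.frame))
  } else {
    data.frame(frame_index = integer(0), headstage = integer(0),
               channel = integer(0), sample = integer(0))
  }
  attr(tuples, "state") <- st
  tuples
}
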