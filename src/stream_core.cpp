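// Core loops of the streaming datapath: frame codec, fixed-point
// Direct-Form-II biquad, three-sample peak detector, and the per-frame
// serial engine that chains them through per-channel state stores.
//
// All fixed-point arithmetic uses 64-bit intermediates; ">> 16" on a
// negative value is an arithmetic (floor) shift, which both gcc and clang
// guarantee for signed integers.

#include <Rcpp.h>
#include <cstring>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// 0x5AFEC0DE5A17E5D1 serialized little-endian.
static const unsigned char SYNC[8] = {0xD1, 0xE5, 0x17, 0x5A,
                                      0xDE, 0xC0, 0xFE, 0x5A};

static inline int frame_nbytes(int n_tot, int payload_kind) {
  int len = 8 + 4 + 2 * n_tot;
  if (payload_kind == 1) len += (n_tot + 7) / 8;
  return len;
}

// ---------------------------------------------------------------- codec --

// [[Rcpp::export]]
RawVector cpp_encode_frames(IntegerMatrix samples, int payload_kind,
                            Nullable<LogicalMatrix> flags_,
                            IntegerVector frame_index) {
  const int n = samples.nrow(), ntot = samples.ncol();
  if ((int)frame_index.size() != n) stop("frame_index length mismatch");
  const int flen = frame_nbytes(ntot, payload_kind);
  RawVector out((R_xlen_t)n * flen);
  LogicalMatrix flags;
  bool have_flags = false;
  if (payload_kind == 1 && flags_.isNotNull()) {
    flags = flags_.get();
    if (flags.nrow() != n || flags.ncol() != ntot) stop("flags shape mismatch");
    have_flags = true;
  }
  unsigned char* p = RAW(out);
  for (int t = 0; t < n; ++t) {
    std::memcpy(p, SYNC, 8); p += 8;
    uint32_t fi = (uint32_t)frame_index[t];
    p[0] = fi & 0xFF; p[1] = (fi >> 8) & 0xFF;
    p[2] = (fi >> 16) & 0xFF; p[3] = (fi >> 24) & 0xFF;
    p += 4;
    for (int c = 0; c < ntot; ++c) {
      int v = samples(t, c);
      if (v < -32768 || v > 32767) stop("sample outside int16 range");
      uint16_t u = (uint16_t)(int16_t)v;
      p[0] = u & 0xFF; p[1] = (u >> 8) & 0xFF;
      p += 2;
    }
    if (payload_kind == 1) {
      int nb = (ntot + 7) / 8;
      std::memset(p, 0, nb);
      if (have_flags)
        for (int c = 0; c < ntot; ++c)
          if (flags(t, c)) p[c >> 3] |= (unsigned char)(1u << (c & 7));
      p += nb;
    }
  }
  return out;
}

struct FrameScan {
  std::vector<R_xlen_t> starts;
  int resync = 0;
  R_xlen_t skipped = 0;
  R_xlen_t tail_at = 0;  // first byte not consumed as a full frame
};

// Frame boundaries are trusted while synchronized; a sync-word mismatch at
// an expected boundary triggers a byte-by-byte scan (one resync event per
// corrupted region).  A trailing region holding a valid sync but less than
// a full frame is the undecodable tail.
static FrameScan scan_frames(const unsigned char* b, R_xlen_t len,
                             R_xlen_t pos, int flen) {
  FrameScan s;
  bool in_sync = true;
  while (pos < len) {
    bool sync_ok = (pos + 8 <= len) && std::memcmp(b + pos, SYNC, 8) == 0;
    if (sync_ok && pos + flen <= len) {
      s.starts.push_back(pos);
      pos += flen;
      in_sync = true;
    } else if (sync_ok || len - pos < 8) {
      break;  // partial trailing frame or remnant too short to judge
    } else {
      if (in_sync) { s.resync++; in_sync = false; }
      pos++;
      s.skipped++;
    }
  }
  s.tail_at = pos;
  return s;
}

// [[Rcpp::export]]
List cpp_decode_frames(RawVector bytes, double offset, int n_hs, int n_ch,
                       int payload_kind, bool keep_tail) {
  const int ntot = n_hs * n_ch;
  const int flen = frame_nbytes(ntot, payload_kind);
  const unsigned char* b = RAW(bytes);
  const R_xlen_t len = bytes.size();
  FrameScan s = scan_frames(b, len, (R_xlen_t)offset, flen);
  const int n = (int)s.starts.size();
  IntegerMatrix samples(n, ntot);
  IntegerVector fidx(n);
  LogicalMatrix flags(payload_kind == 1 ? n : 0, payload_kind == 1 ? ntot : 0);
  for (int t = 0; t < n; ++t) {
    const unsigned char* p = b + s.starts[t] + 8;
    fidx[t] = (int)(p[0] | (p[1] << 8) | (p[2] << 16) | ((uint32_t)p[3] << 24));
    p += 4;
    for (int c = 0; c < ntot; ++c) {
      samples(t, c) = (int16_t)(p[0] | (p[1] << 8));
      p += 2;
    }
    if (payload_kind == 1)
      for (int c = 0; c < ntot; ++c)
        flags(t, c) = (p[c >> 3] >> (c & 7)) & 1;
  }
  RawVector tail(0);
  double dropped_tail = 0;
  if (s.tail_at < len) {
    if (keep_tail) {
      tail = RawVector(len - s.tail_at);
      std::memcpy(RAW(tail), b + s.tail_at, len - s.tail_at);
    } else {
      dropped_tail = (double)(len - s.tail_at);
    }
  }
  return List::create(
      _["samples"] = samples, _["frame_index"] = fidx, _["flags"] = flags,
      _["frames_decoded"] = n, _["resync_events"] = s.resync,
      _["bytes_skipped"] = (double)s.skipped, _["tail"] = tail,
      _["trailing_bytes_dropped"] = dropped_tail);
}

// --------------------------------------------------------------- filter --

struct FiltQ { int64_t b0, b1, b2, a1, a2; };

// int32 saturation avoids INT32_MIN, which R reserves as NA_integer_.
static inline int32_t sat32(int64_t v, long* nsat) {
  if (v > (int64_t)INT32_MAX) { (*nsat)++; return INT32_MAX; }
  if (v < -(int64_t)INT32_MAX) { (*nsat)++; return -INT32_MAX; }
  return (int32_t)v;
}

// One Direct-Form-II step in Q2.16 fixed point.  Input x is a 16-bit
// sample in ADC counts; states live at counts << 16; the output is
// rescaled to counts with round-to-nearest (half toward +inf).
static inline int biquad_step_core(int x, int32_t& w1, int32_t& w2,
                                   const FiltQ& q, long* nsat) {
  int64_t fb = q.a1 * (int64_t)w1 + q.a2 * (int64_t)w2;
  int64_t w64 = ((int64_t)x << 16) - (fb >> 16);
  int32_t w = sat32(w64, nsat);
  int64_t ff = q.b0 * (int64_t)w + q.b1 * (int64_t)w1 + q.b2 * (int64_t)w2;
  int64_t ystate = ff >> 16;
  int64_t y = (ystate + 32768) >> 16;
  w2 = w1;
  w1 = w;
  return (int)y;
}

static FiltQ as_filtq(IntegerVector q5) {
  if (q5.size() != 5) stop("need 5 quantized coefficients");
  FiltQ q;
  q.b0 = q5[0]; q.b1 = q5[1]; q.b2 = q5[2]; q.a1 = q5[3]; q.a2 = q5[4];
  return q;
}

// [[Rcpp::export]]
List cpp_filter_batch(IntegerVector x, IntegerVector q5, IntegerVector state) {
  FiltQ q = as_filtq(q5);
  if (state.size() != 2) stop("filter state must have length 2");
  int32_t w1 = state[0], w2 = state[1];
  long nsat = 0;
  R_xlen_t n = x.size();
  IntegerVector y(n);
  for (R_xlen_t i = 0; i < n; ++i)
    y[i] = biquad_step_core(x[i], w1, w2, q, &nsat);
  return List::create(_["y"] = y,
                      _["state"] = IntegerVector::create(w1, w2),
                      _["n_saturated"] = (double)nsat);
}

// ------------------------------------------------------------- detector --

struct DetSt { int y1, y2, refr; double seen; };

// Three-sample negative-peak rule with a per-channel refractory counter.
// While the counter is active the conditions are not evaluated at all and
// the counter is decremented once per call (one call == one acquisition
// loop for that channel).
static inline bool detect_step_core(int y, DetSt& st, int thr, int refr_n) {
  bool spike = false;
  if (st.refr > 0) {
    st.refr -= 1;
  } else if (st.seen >= 2 && st.y1 < y && st.y1 <= st.y2 && st.y1 < thr) {
    spike = true;
    st.refr = refr_n;
  }
  st.y2 = st.y1;
  st.y1 = y;
  st.seen += 1;
  return spike;
}

// [[Rcpp::export]]
List cpp_detect_batch(IntegerVector y, int threshold_counts,
                      int refractory_samples, IntegerVector state3,
                      double seen) {
  if (state3.size() != 3) stop("detector state must have length 3");
  DetSt st;
  st.y1 = state3[0]; st.y2 = state3[1]; st.refr = state3[2]; st.seen = seen;
  std::vector<double> ev;
  R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double ord = st.seen;  // ordinal of the sample being consumed
    if (detect_step_core(y[i], st, threshold_counts, refractory_samples))
      ev.push_back(ord - 1);  // peak is the previous sample
  }
  return List::create(
      _["events"] = NumericVector(ev.begin(), ev.end()),
      _["state"] = IntegerVector::create(st.y1, st.y2, st.refr),
      _["seen"] = st.seen);
}

// --------------------------------------------------------------- engine --

// One shared filter/detector datapath visits the channels of each frame in
// serialization order (channel-major: column p maps to ch = p / n_hs,
// hs = p %% n_hs), fetching and writing per-channel state in 128 fixed
// slots addressed as hs * 16 + ch.
// [[Rcpp::export]]
List cpp_process_frames(IntegerMatrix samples, int n_hs, int n_ch,
                        IntegerVector q5, int threshold_counts,
                        int refractory_samples, IntegerVector w1_,
                        IntegerVector w2_, IntegerVector dy1_,
                        IntegerVector dy2_, IntegerVector drefr_,
                        NumericVector dseen_) {
  const int n = samples.nrow(), ntot = n_hs * n_ch;
  if (samples.ncol() != ntot) stop("sample matrix shape mismatch");
  if (w1_.size() != 128 || w2_.size() != 128 || dy1_.size() != 128 ||
      dy2_.size() != 128 || drefr_.size() != 128 || dseen_.size() != 128)
    stop("state stores must hold 128 slots");
  FiltQ q = as_filtq(q5);
  IntegerVector w1 = clone(w1_), w2 = clone(w2_);
  IntegerVector dy1 = clone(dy1_), dy2 = clone(dy2_), drefr = clone(drefr_);
  NumericVector dseen = clone(dseen_);
  IntegerMatrix filt(n, ntot);
  LogicalMatrix flags(n, ntot);
  std::vector<int> ev_hs, ev_ch;
  std::vector<double> ev_idx;
  long nsat = 0, ysat = 0;
  for (int t = 0; t < n; ++t) {
    for (int p = 0; p < ntot; ++p) {
      const int ch = p / n_hs, hs = p % n_hs;
      const int slot = hs * 16 + ch;
      int32_t a = w1[slot], b = w2[slot];
      int y = biquad_step_core(samples(t, p), a, b, q, &nsat);
      w1[slot] = a; w2[slot] = b;
      DetSt st;
      st.y1 = dy1[slot]; st.y2 = dy2[slot];
      st.refr = drefr[slot]; st.seen = dseen[slot];
      double ord = st.seen;
      bool spike = detect_step_core(y, st, threshold_counts, refractory_samples);
      dy1[slot] = st.y1; dy2[slot] = st.y2;
      drefr[slot] = st.refr; dseen[slot] = st.seen;
      int yo = y;
      if (yo > 32767) { yo = 32767; ysat++; }
      else if (yo < -32768) { yo = -32768; ysat++; }
      filt(t, p) = yo;
      flags(t, p) = spike;
      if (spike) {
        ev_hs.push_back(hs);
        ev_ch.push_back(ch);
        ev_idx.push_back(ord - 1);
      }
    }
  }
  return List::create(
      _["filtered"] = filt, _["flags"] = flags,
      _["event_headstage"] = IntegerVector(ev_hs.begin(), ev_hs.end()),
      _["event_channel"] = IntegerVector(ev_ch.begin(), ev_ch.end()),
      _["event_sample_index"] = NumericVector(ev_idx.begin(), ev_idx.end()),
      _["filter_states"] = List::create(_["w1"] = w1, _["w2"] = w2),
      _["detector_states"] = List::create(_["y1"] = dy1, _["y2"] = dy2,
                                          _["refractory"] = drefr,
                                          _["seen"] = dseen),
      _["n_state_saturated"] = (double)nsat,
      _["n_output_saturated"] = (double)ysat);
}
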