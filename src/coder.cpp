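#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Range coder: 32-bit range, 64-bit low with carry propagation, byte output.
// Layout documented bit-exactly in FORMAT.md. The coder is static: every
// symbol carries its own quantized CDF (cumulative counts summing to
// 2^precision); encoder and decoder must be fed identical CDFs.
// ---------------------------------------------------------------------------

static const uint32_t kTopValue = 1u << 24;

struct RangeEncoder {
  uint64_t low;
  uint32_t range;
  uint8_t cache;
  uint64_t cache_size;
  std::vector<uint8_t> out;
  RangeEncoder() : low(0), range(0xFFFFFFFFu), cache(0), cache_size(1) {}
  void shift_low() {
    if ((uint32_t)low < 0xFF000000u || (low >> 32) != 0) {
      uint8_t carry = (uint8_t)(low >> 32);
      uint8_t temp = cache;
      do {
        out.push_back((uint8_t)(temp + carry));
        temp = 0xFF;
      } while (--cache_size != 0);
      cache = (uint8_t)(low >> 24);
    }
    cache_size++;
    low = (uint32_t)low << 8;
  }
  void encode(uint32_t cum, uint32_t freq, uint32_t tot) {
    uint32_t r = range / tot;
    low += (uint64_t)r * cum;
    range = r * freq;
    while (range < kTopValue) {
      range <<= 8;
      shift_low();
    }
  }
  void flush() {
    for (int i = 0; i < 5; i++) shift_low();
  }
};

struct RangeDecoder {
  const uint8_t *buf;
  size_t len, pos;
  uint32_t range, code;
  bool overrun;
  RangeDecoder(const uint8_t *b, size_t n)
      : buf(b), len(n), pos(0), range(0xFFFFFFFFu), code(0), overrun(false) {
    for (int i = 0; i < 5; i++) code = (code << 8) | next_byte();
  }
  uint8_t next_byte() {
    if (pos >= len) { overrun = true; return 0; }
    return buf[pos++];
  }
  uint32_t get_freq(uint32_t tot) {
    range /= tot;
    uint32_t f = code / range;
    return f >= tot ? tot - 1 : f;
  }
  void decode_update(uint32_t cum, uint32_t freq) {
    code -= cum * range;
    range *= freq;
    while (range < kTopValue) {
      code = (code << 8) | next_byte();
      range <<= 8;
    }
  }
};

// Largest-remainder quantization of a 511-class pmf to integer counts summing
// to 2^precision, every class forced to >= 1 count (mass borrowed from the
// largest classes).  Returns counts, length n_classes.
static void quantize_counts(const double *p, int nc, int precision,
                            std::vector<uint32_t> &counts) {
  uint32_t total = 1u << precision;
  double s = 0.0;
  for (int k = 0; k < nc; k++) s += (p[k] > 0 ? p[k] : 0.0);
  if (s <= 0.0) s = 1.0;
  counts.assign(nc, 0);
  static thread_local std::vector<std::pair<double, int> > frac;
  frac.resize(nc);
  uint64_t assigned = 0;
  for (int k = 0; k < nc; k++) {
    double scaled = (p[k] > 0 ? p[k] : 0.0) / s * (double)total;
    double fl = std::floor(scaled);
    counts[k] = (uint32_t)fl;
    assigned += counts[k];
    frac[k] = std::make_pair(-(scaled - fl), k); // ascending = largest frac first
  }
  int64_t deficit = (int64_t)total - (int64_t)assigned;
  if (deficit > 0) {
    // pairs are unique (index tie-break), so plain sort is deterministic
    int64_t d = deficit < nc ? deficit : nc;
    std::partial_sort(frac.begin(), frac.begin() + d, frac.end());
    for (int64_t i = 0; i < deficit; i++) counts[frac[i % nc].second] += 1;
  }
  // enforce minimum one count per class
  int64_t needed = 0;
  for (int k = 0; k < nc; k++) if (counts[k] == 0) { counts[k] = 1; needed++; }
  while (needed > 0) {
    int big = 0;
    for (int k = 1; k < nc; k++) if (counts[k] > counts[big]) big = k;
    uint32_t take = (uint32_t)std::min<int64_t>(needed, (int64_t)counts[big] - 1);
    if (take == 0) stop("cannot enforce minimum counts: precision too small");
    counts[big] -= take;
    needed -= take;
  }
}

// [[Rcpp::export(name = ".quantize_pmf_cpp")]]
IntegerVector quantize_pmf_cpp(NumericVector pmf, int precision) {
  int nc = pmf.size();
  std::vector<uint32_t> counts;
  quantize_counts(REAL(pmf), nc, precision, counts);
  IntegerVector cum(nc + 1);
  uint32_t acc = 0;
  cum[0] = 0;
  for (int k = 0; k < nc; k++) {
    acc += counts[k];
    cum[k + 1] = (int)acc;
  }
  return cum;
}

// Encode symbols (0-based classes) under per-symbol CDFs given as an
// integer matrix n x (nc+1) of cumulative counts.
// [[Rcpp::export(name = ".rc_encode_cum_cpp")]]
RawVector rc_encode_cum_cpp(IntegerVector symbols, IntegerMatrix cum, int precision) {
  int n = symbols.size();
  if (cum.nrow() != n) stop("one CDF row per symbol required");
  uint32_t tot = 1u << precision;
  RangeEncoder enc;
  int nc = cum.ncol() - 1;
  for (int i = 0; i < n; i++) {
    int s = symbols[i];
    if (s < 0 || s >= nc) stop("symbol out of range");
    uint32_t lo = (uint32_t)cum(i, s);
    uint32_t hi = (uint32_t)cum(i, s + 1);
    if (hi <= lo) stop("zero-frequency symbol in CDF");
    enc.encode(lo, hi - lo, tot);
  }
  enc.flush();
  RawVector out(enc.out.size());
  std::copy(enc.out.begin(), enc.out.end(), RAW(out));
  return out;
}

// [[Rcpp::export(name = ".rc_decode_cum_cpp")]]
IntegerVector rc_decode_cum_cpp(RawVector stream, IntegerMatrix cum, int n, int precision) {
  uint32_t tot = 1u << precision;
  RangeDecoder dec(RAW(stream), stream.size());
  int nc = cum.ncol() - 1;
  IntegerVector out(n);
  for (int i = 0; i < n; i++) {
    uint32_t f = dec.get_freq(tot);
    // binary search: largest s with cum[s] <= f
    int lo = 0, hi = nc;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if ((uint32_t)cum(i, mid) <= f) lo = mid; else hi = mid;
    }
    uint32_t c = (uint32_t)cum(i, lo), cn = (uint32_t)cum(i, lo + 1);
    dec.decode_update(c, cn - c);
    if (dec.overrun) stop("corrupt or truncated stream");
    out[i] = lo;
  }
  return out;
}

// Fused path for images: quantize each pmf row and encode in one pass.
// pmfs: n x nc matrix (row i = distribution of symbol i).
// [[Rcpp::export(name = ".rc_encode_pmf_cpp")]]
RawVector rc_encode_pmf_cpp(NumericMatrix pmfs, IntegerVector symbols, int precision) {
  int n = symbols.size();
  if (pmfs.nrow() != n) stop("one pmf row per symbol required");
  int nc = pmfs.ncol();
  uint32_t tot = 1u << precision;
  RangeEncoder enc;
  std::vector<double> row(nc);
  std::vector<uint32_t> counts;
  for (int i = 0; i < n; i++) {
    for (int k = 0; k < nc; k++) row[k] = pmfs(i, k);
    quantize_counts(row.data(), nc, precision, counts);
    int s = symbols[i];
    if (s < 0 || s >= nc) stop("symbol out of range");
    uint32_t lo = 0;
    for (int k = 0; k < s; k++) lo += counts[k];
    enc.encode(lo, counts[s], tot);
  }
  enc.flush();
  RawVector out(enc.out.size());
  std::copy(enc.out.begin(), enc.out.end(), RAW(out));
  return out;
}

// [[Rcpp::export(name = ".rc_decode_pmf_cpp")]]
IntegerVector rc_decode_pmf_cpp(NumericMatrix pmfs, RawVector stream, int n, int precision) {
  if (pmfs.nrow() != n) stop("one pmf row per symbol required");
  int nc = pmfs.ncol();
  uint32_t tot = 1u << precision;
  RangeDecoder dec(RAW(stream), stream.size());
  IntegerVector out(n);
  std::vector<double> row(nc);
  std::vector<uint32_t> counts, cum(nc + 1);
  for (int i = 0; i < n; i++) {
    for (int k = 0; k < nc; k++) row[k] = pmfs(i, k);
    quantize_counts(row.data(), nc, precision, counts);
    cum[0] = 0;
    for (int k = 0; k < nc; k++) cum[k + 1] = cum[k] + counts[k];
    uint32_t f = dec.get_freq(tot);
    int lo = 0, hi = nc;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (cum[mid] <= f) lo = mid; else hi = mid;
    }
    dec.decode_update(cum[lo], counts[lo]);
    if (dec.overrun) stop("corrupt or truncated stream");
    out[i] = lo;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Checksums / digests
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".crc32_cpp")]]
double crc32_cpp(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; i++) {
      uint32_t c = i;
      for (int k = 0; k < 8; k++) c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); i++)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}

// [[Rcpp::export(name = ".fnv64_cpp")]]
String fnv64_cpp(RawVector data) {
  uint64_t h = 1469598103934665603ull;
  for (R_xlen_t i = 0; i < data.size(); i++) {
    h ^= (uint64_t)data[i];
    h *= 1099511628211ull;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return String(buf);
}
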