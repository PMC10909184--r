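# The `.lfc` container format (version 1)

A compressed image is a single byte string: a fixed 44-byte header
followed by four payloads. All multi-byte integers are little-endian
unsigned.

## Header (44 bytes)

| offset | size | field |
|-------:|-----:|-------|
| 0  | 4 | magic `4C 46 43 31` (`"LFC1"`) |
| 4  | 1 | format version (1) |
| 5  | 1 | base codec id: 0 = store, 1 = PNG, 2 = JPEG-XL |
| 6  | 1 | pad flags: bit 0 = a bottom row was edge-replicated, bit 1 = a right column was |
| 7  | 1 | CDF precision in bits (default 16) |
| 8  | 4 | original image width in pixels |
| 12 | 4 | original image height in pixels |
| 16 | 8 | model version hash (FNV-1a 64-bit over the serialized parameters and configuration), big-endian byte order of the hex digest |
| 24 | 4 | CRC-32 (polynomial `0xEDB88320`, reflected) of the original pixels, taken over the pixel values as bytes in column-major order |
| 28 | 4 | byte length of payload A |
| 32 | 4 | byte length of payload D |
| 36 | 4 | byte length of payload B |
| 40 | 4 | byte length of payload C |

The decoder refuses the stream unless the magic, version and model hash
match, the payload lengths reconcile with the stream length, and -- after
full reconstruction -- the CRC-32 matches.

## Subimage geometry

The image is edge-replicated to even width/height if needed (recorded in
the pad flags), then split on the 2x2 lattice: with 1-based indexing,
subimage A = odd rows/odd columns, B = odd/even, C = even/odd,
D = even/even. All four subimages are `ceil(H/2) x ceil(W/2)`.

## Payloads

* **A** — the base codec's own byte stream for subimage A (e.g. a
  complete PNG file).
* **D, B, C** (in this coding order) — range-coded residual classes, one
  per subimage pixel in column-major order. The residual class of a pixel
  is `(actual - predicted) + 255` with the prediction integerized
  (rounded half away from zero, clipped to [0, 255]), so classes occupy
  [0, 510]. The per-pixel 511-class distributions come from the model
  given all previously decoded subimages; encoder and decoder quantize
  them identically (below), so no distribution data is stored.

## CDF quantization

Each per-pixel probability vector is converted to integer counts summing
to `2^precision` by largest-remainder rounding; every class is then
raised to a minimum count of 1, the excess repeatedly taken from the
currently largest class (ties broken toward the lowest class index).
Cumulative counts `cum[0..511]`, `cum[0] = 0`, `cum[511] = 2^precision`,
define each symbol's interval `[cum[s], cum[s+1])`.

## Range coder

A carry-propagating byte-oriented range coder with 32-bit range and
64-bit low:

* State: `low` (64-bit, initially 0), `range` (32-bit, initially
  `0xFFFFFFFF`), a pending `cache` byte (initially 0) and a pending-run
  counter `cache_size` (initially 1).
* Encoding symbol `s` with total `T = 2^precision`:
  `r = range / T` (integer division), `low += r * cum[s]`,
  `range = r * (cum[s+1] - cum[s])`.
* Renormalization: while `range < 2^24`, `range <<= 8` and a byte is
  shifted out of `low` (LZMA-style `shift_low`: when `low < 0xFF000000`
  or a carry is pending, emit `cache + carry` followed by the pending run
  of `0xFF + carry` bytes; then `cache = byte 3 of low`,
  `low = (low << 8) & 0xFFFFFFFFFF`).
* Flush: five final `shift_low` steps. The first emitted byte of every
  stream is therefore a leading 0 (or carry) byte; total terminator
  overhead is at most 6 bytes.
* Decoding mirrors this: initialize `code` from the first 5 bytes,
  `r = range / T`, symbol found by binary search of `code / r` in the
  cumulative counts, then `code -= r * cum[s]`, `range = r * freq`,
  refilling bytes while `range < 2^24`. Reading past the end of a
  payload is a corrupt-stream error.

An empty symbol sequence encodes to the flush bytes alone and decodes to
an empty sequence.
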