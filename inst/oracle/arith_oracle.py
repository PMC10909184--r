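#!/usr/bin/env python
"""Exact arithmetic-coding oracle.

Reads JSON on stdin:
  {"total": 65536,
   "instances": [{"symbols": [..0-based..],
                  "cum": [[c0..cK] per symbol]} , ...]}

For each instance, performs exact interval arithmetic coding with
rational arithmetic (no finite-precision renormalization): the final
interval [low, low+width) is computed exactly, the code is the shortest
binary fraction inside it, and decoding recovers the symbols from that
fraction alone.  Emits JSON:
  {"results": [{"bits": k, "decoded": [...], "ok": true}, ...]}

This is an independent reference for the package's range coder: it
shares nothing with the C++ implementation beyond the CDF convention.
"""
import json
import sys
from fractions import Fraction


def encode_exact(symbols, cums, total):
    low = Fraction(0)
    width = Fraction(1)
    for s, cum in zip(symbols, cums):
        lo, hi = cum[s], cum[s + 1]
        low += width * Fraction(lo, total)
        width *= Fraction(hi - lo, total)
    # shortest k with a binary fraction v/2^k in [low, low + width)
    k = 0
    while Fraction(1, 2 ** k) > width:
        k += 1
    v = -((-low.numerator * 2 ** k) // low.denominator)  # ceil(low * 2^k)
    assert Fraction(v, 2 ** k) >= low
    assert Fraction(v, 2 ** k) < low + width
    return v, k


def decode_exact(v, k, cums, total, n):
    f = Fraction(v, 2 ** k)
    low = Fraction(0)
    width = Fraction(1)
    out = []
    for i in range(n):
        t = (f - low) / width            # in [0, 1)
        j = (t.numerator * total) // t.denominator
        cum = cums[i]
        # find s with cum[s] <= j < cum[s+1]
        lo_i, hi_i = 0, len(cum) - 1
        while hi_i - lo_i > 1:
            mid = (lo_i + hi_i) // 2
            if cum[mid] <= j:
                lo_i = mid
            else:
                hi_i = mid
        s = lo_i
        out.append(s)
        low += width * Fraction(cum[s], total)
        width *= Fraction(cum[s + 1] - cum[s], total)
    return out


def main():
    req = json.load(sys.stdin)
    total = req["total"]
    if isinstance(total, list):
        total = total[0]
    results = []
    for inst in req["instances"]:
        symbols = inst["symbols"]
        cums = inst["cum"]
        if len(cums) == 1 and len(symbols) > 1:
            cums = cums * len(symbols)
        v, k = encode_exact(symbols, cums, total)
        dec = decode_exact(v, k, cums, total, len(symbols))
        results.append({"bits": k, "decoded": dec, "ok": dec == symbols})
    json.dump({"results": results}, sys.stdout)


if __name__ == "__main__":
    main()
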