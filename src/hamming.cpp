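#include <Rcpp.h>
#include <cstring>
#include <cstdint>
using namespace Rcpp;

// Count of non-zero bytes in x (i.e. mismatching characters after XOR).
static inline int nonzero_bytes(uint64_t x) {
    uint64_t t = x;
    t |= t >> 1;
    t |= t >> 2;
    t |= t >> 4;
    t &= 0x0101010101010101ULL;
#if defined(__GNUC__) || defined(__clang__)
    return __builtin_popcountll(t);
#else
    int c = 0;
    while (t) { t &= t - 1; ++c; }
    return c;
#endif
}

// Hamming mismatches between a[0..n) and b[0..n), stopping at cutoff + 1.
// Processes 8 characters per step; any characters that differ count as
// mismatches, so an N in the read mismatches every reference base.
static inline int mm_count(const char* a, const char* b, int n, int cutoff) {
    int mm = 0, i = 0;
    for (; i + 8 <= n; i += 8) {
        uint64_t x, y;
        std::memcpy(&x, a + i, 8);
        std::memcpy(&y, b + i, 8);
        if (x != y) {
            mm += nonzero_bytes(x ^ y);
            if (mm > cutoff) return cutoff + 1;
        }
    }
    for (; i < n; ++i) {
        if (a[i] != b[i] && ++mm > cutoff) return cutoff + 1;
    }
    return mm;
}

// Mismatch counts of `pattern` against `subject` at given 1-based starts;
// cutoff + 1 signals "more than cutoff" (or an out-of-range start).
// [[Rcpp::export(name = ".hammingAt")]]
IntegerVector hamming_at(const std::string& subject, const std::string& pattern,
                         const IntegerVector& starts, const int cutoff) {
    const int n = pattern.size();
    const int L = subject.size();
    const int m = starts.size();
    IntegerVector out(m);
    for (int j = 0; j < m; ++j) {
        const int s = starts[j] - 1;
        out[j] = (s < 0 || s + n > L) ? cutoff + 1
            : mm_count(subject.data() + s, pattern.data(), n, cutoff);
    }
    return out;
}

// Full scan of every start position; returns the 1-based starts with
// mismatch count <= cutoff and their scores. Used by the brute-force
// mapping oracle.
// [[Rcpp::export(name = ".hammingScan")]]
List hamming_scan(const std::string& subject, const std::string& pattern,
                  const int cutoff) {
    const int n = pattern.size();
    const int L = subject.size();
    std::vector<int> starts;
    std::vector<int> scores;
    for (int s = 0; s + n <= L; ++s) {
        const int mm = mm_count(subject.data() + s, pattern.data(), n, cutoff);
        if (mm <= cutoff) {
            starts.push_back(s + 1);
            scores.push_back(mm);
        }
    }
    return List::create(_["start"] = wrap(starts), _["score"] = wrap(scores));
}
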