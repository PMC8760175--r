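#include <Rcpp.h>
#include <cstdint>

// 32-bit FNV-1a over UTF-8 bytes. Returned as double because R has no
// native unsigned 32-bit type; values are exact integers < 2^32.
// [[Rcpp::export]]
Rcpp::NumericVector fnv1a32(Rcpp::CharacterVector x) {
  const uint32_t prime = 16777619u;
  R_xlen_t n = x.size();
  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) {
      out[i] = NA_REAL;
      continue;
    }
    const char *s = CHAR(x[i]);
    uint32_t h = 2166136261u;
    for (; *s; ++s) {
      h ^= static_cast<uint8_t>(*s);
      h *= prime;
    }
    out[i] = static_cast<double>(h);
  }
  return out;
}
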