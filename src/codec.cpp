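#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <stdexcept>

using namespace Rcpp;

// 64-bit variant identifiers travel through R as decimal strings because R's
// double mantissa (53 bits) cannot hold all 63-bit values exactly.

static uint64_t parse_u64(const String& s, int i) {
  if (s == NA_STRING) stop("id %d is NA", i + 1);
  const char* c = s.get_cstring();
  if (*c == '\0') stop("id %d is empty", i + 1);
  uint64_t v = 0;
  for (const char* p = c; *p != '\0'; ++p) {
    if (*p < '0' || *p > '9')
      stop("id %d ('%s') is not a non-negative 64-bit integer", i + 1, c);
    uint64_t d = (uint64_t)(*p - '0');
    if (v > (UINT64_MAX - d) / 10)
      stop("id %d ('%s') overflows 64 bits", i + 1, c);
    v = v * 10 + d;
  }
  return v;
}

static int base4(char c, int i) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  stop("non-ACGT character '%c' in allele of variant %d", c, i + 1);
  return -1;  // unreachable
}

// Shared prefix removed first (advancing pos), then shared suffix.
// [[Rcpp::export]]
DataFrame cpp_trim_alleles(IntegerVector chrom, IntegerVector pos,
                           CharacterVector ref, CharacterVector alt) {
  int n = chrom.size();
  IntegerVector opos(n);
  CharacterVector oref(n), oalt(n);
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(ref[i]), a = as<std::string>(alt[i]);
    if (r == a) stop("ref equals alt for variant %d", i + 1);
    size_t p = 0;
    while (p < r.size() && p < a.size() && r[p] == a[p]) ++p;
    size_t s = 0;
    while (s + p < r.size() && s + p < a.size() &&
           r[r.size() - 1 - s] == a[a.size() - 1 - s]) ++s;
    opos[i] = pos[i] + (int)p;
    oref[i] = r.substr(p, r.size() - p - s);
    oalt[i] = a.substr(p, a.size() - p - s);
  }
  return DataFrame::create(_["chrom"] = chrom, _["pos"] = opos,
                           _["ref"] = oref, _["alt"] = oalt,
                           _["stringsAsFactors"] = false);
}

// id = c*2^58 + p*2^30 + |r|*2^24 + |a|*2^18 + sum_i A_i 4^(i-1), where A is
// the alt allele when shorter than 10 bases, else its first five plus last
// four bases. Length fields saturate at 63; saturation or |alt| >= 10 makes
// the encoding ambiguous (full alleles must be kept elsewhere).
// [[Rcpp::export]]
DataFrame cpp_encode_rsvr(IntegerVector chrom, IntegerVector pos,
                          CharacterVector ref, CharacterVector alt) {
  const uint64_t POS_MAX = (1ull << 28);
  int n = chrom.size();
  CharacterVector id(n);
  LogicalVector ambiguous(n);
  for (int i = 0; i < n; ++i) {
    int c = chrom[i];
    if (c < 1 || c > 25) stop("chromosome code %d of variant %d outside 1-25", c, i + 1);
    if (pos[i] < 0 || (uint64_t)pos[i] >= POS_MAX)
      stop("position %d of variant %d does not fit in 28 bits", pos[i], i + 1);
    std::string r = as<std::string>(ref[i]), a = as<std::string>(alt[i]);
    uint64_t rl = r.size(), al = a.size();
    std::string A = a;
    if (al >= 10) A = a.substr(0, 5) + a.substr(al - 4, 4);
    uint64_t code = 0, mult = 1;
    for (size_t k = 0; k < A.size(); ++k) {
      code += (uint64_t)base4(A[k], i) * mult;
      mult *= 4;
    }
    bool amb = (al >= 10) || (rl > 63) || (al > 63);
    uint64_t v = ((uint64_t)c << 58) | ((uint64_t)pos[i] << 30) |
                 (std::min<uint64_t>(rl, 63) << 24) |
                 (std::min<uint64_t>(al, 63) << 18) | code;
    id[i] = std::to_string(v);
    ambiguous[i] = amb;
  }
  return DataFrame::create(_["id"] = id, _["ambiguous"] = ambiguous,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_decode_rsvr(CharacterVector id) {
  int n = id.size();
  IntegerVector chrom(n), pos(n), rlen(n), alen(n);
  CharacterVector alt(n);
  LogicalVector partial(n);
  const char* nuc = "ACGT";
  for (int i = 0; i < n; ++i) {
    uint64_t v = parse_u64(id[i], i);
    if (v >> 63) stop("id %d has its most significant bit set (structural variant)", i + 1);
    chrom[i] = (int)(v >> 58);
    pos[i] = (int)((v >> 30) & ((1ull << 28) - 1));
    rlen[i] = (int)((v >> 24) & 63);
    alen[i] = (int)((v >> 18) & 63);
    uint64_t code = v & ((1ull << 18) - 1);
    int stored = alen[i] < 10 ? alen[i] : 9;
    std::string a(stored, 'A');
    for (int k = 0; k < stored; ++k) {
      a[k] = nuc[code & 3];
      code >>= 2;
    }
    alt[i] = a;
    partial[i] = alen[i] >= 10;
  }
  return DataFrame::create(_["chrom"] = chrom, _["pos"] = pos,
                           _["ref_len"] = rlen, _["alt_len"] = alen,
                           _["alt"] = alt, _["partial"] = partial,
                           _["stringsAsFactors"] = false);
}

// Structural variants: MSB set, then type (2 bits), chrom (5), start (28),
// length (28).
// [[Rcpp::export]]
CharacterVector cpp_encode_sv(IntegerVector type, IntegerVector chrom,
                              IntegerVector start, IntegerVector len) {
  const uint64_t F28 = (1ull << 28);
  int n = type.size();
  CharacterVector id(n);
  for (int i = 0; i < n; ++i) {
    if (type[i] < 0 || type[i] > 3) stop("sv type %d of record %d outside 0-3", type[i], i + 1);
    if (chrom[i] < 1 || chrom[i] > 25) stop("chromosome code of record %d outside 1-25", i + 1);
    if (start[i] < 0 || (uint64_t)start[i] >= F28) stop("start of record %d does not fit in 28 bits", i + 1);
    if (len[i] < 0 || (uint64_t)len[i] >= F28) stop("length of record %d does not fit in 28 bits", i + 1);
    uint64_t v = (1ull << 63) | ((uint64_t)type[i] << 61) |
                 ((uint64_t)chrom[i] << 56) | ((uint64_t)start[i] << 28) |
                 (uint64_t)len[i];
    id[i] = std::to_string(v);
  }
  return id;
}

// [[Rcpp::export]]
DataFrame cpp_decode_sv(CharacterVector id) {
  int n = id.size();
  IntegerVector type(n), chrom(n), start(n), len(n);
  for (int i = 0; i < n; ++i) {
    uint64_t v = parse_u64(id[i], i);
    if (!(v >> 63)) stop("id %d is not a structural-variant id (MSB unset)", i + 1);
    type[i] = (int)((v >> 61) & 3);
    chrom[i] = (int)((v >> 56) & 31);
    start[i] = (int)((v >> 28) & ((1ull << 28) - 1));
    len[i] = (int)(v & ((1ull << 28) - 1));
  }
  return DataFrame::create(_["sv_type"] = type, _["chrom"] = chrom,
                           _["start"] = start, _["length"] = len);
}

// Order permutation (1-based) of ids by their unsigned 64-bit value.
// [[Rcpp::export]]
IntegerVector cpp_u64_order(CharacterVector id) {
  int n = id.size();
  std::vector<std::pair<uint64_t, int>> v(n);
  for (int i = 0; i < n; ++i) v[i] = {parse_u64(id[i], i), i};
  std::stable_sort(v.begin(), v.end());
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = v[i].second + 1;
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_u64_lt(CharacterVector a, CharacterVector b) {
  int n = a.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = parse_u64(a[i], i) < parse_u64(b[i], i);
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_is_sv_id(CharacterVector id) {
  int n = id.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (parse_u64(id[i], i) >> 63) != 0;
  return out;
}
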