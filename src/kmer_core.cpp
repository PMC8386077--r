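// Dense k-mer presence scanning over the full |alphabet|^k word space.
//
// Words are addressed as base-|alphabet| integers (first character most
// significant) into a packed bitmap: 4^15 bits = 128 MB, 20^7 bits = 160 MB,
// both within the memory contract.  Windows overlapping an invalid residue
// (N for DNA, X for protein) are never marked present.

#include <Rcpp.h>
#include <unordered_map>
#include <set>
#include <string>
#include <vector>
using namespace Rcpp;

static inline void make_code(const std::string& letters, int* tab) {
  for (int i = 0; i < 256; ++i) tab[i] = -1;
  for (size_t i = 0; i < letters.size(); ++i)
    tab[(unsigned char)letters[i]] = (int)i;
}

static inline uint64_t upow(uint64_t a, int k) {
  uint64_t r = 1;
  for (int i = 0; i < k; ++i) r *= a;
  return r;
}

// reverse complement of a 2-bit encoded DNA word
static inline uint64_t rc_index(uint64_t v, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) { r = (r << 2) | (3 - (v & 3)); v >>= 2; }
  return r;
}

static inline std::string decode_word(uint64_t v, int k, const std::string& letters) {
  uint64_t A = letters.size();
  std::string w(k, ' ');
  for (int i = k - 1; i >= 0; --i) { w[i] = letters[v % A]; v /= A; }
  return w;
}

static inline bool bit_get(const Rbyte* bm, uint64_t idx) {
  return (bm[idx >> 3] >> (idx & 7)) & 1;
}
static inline void bit_set(Rbyte* bm, uint64_t idx) {
  bm[idx >> 3] |= (Rbyte)(1u << (idx & 7));
}

// [[Rcpp::export]]
RawVector cpp_scan_presence(CharacterVector seqs, int k, std::string letters,
                            bool both) {
  int tab[256]; make_code(letters, tab);
  const uint64_t A = letters.size();
  const uint64_t nwords = upow(A, k);
  const uint64_t Pk1 = upow(A, k - 1);
  RawVector bm((R_xlen_t)((nwords + 7) / 8));  // zero-initialised
  Rbyte* b = bm.begin();
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    const char* s = CHAR(STRING_ELT(seqs, si));
    uint64_t val = 0, rcv = 0;
    int run = 0;
    for (const char* p = s; *p; ++p) {
      int c = tab[(unsigned char)*p];
      if (c < 0) { run = 0; val = 0; rcv = 0; continue; }
      val = (val % Pk1) * A + (uint64_t)c;
      if (both) rcv = rcv / A + (uint64_t)(3 - c) * Pk1;
      if (++run >= k) {
        bit_set(b, val);
        if (both) bit_set(b, rcv);
      }
    }
  }
  return bm;
}

// [[Rcpp::export]]
double cpp_presence_count(RawVector bitmap, double nwords) {
  const uint64_t n = (uint64_t)nwords;
  const Rbyte* b = bitmap.begin();
  uint64_t full = n / 8, cnt = 0;
  for (uint64_t i = 0; i < full; ++i)
    cnt += __builtin_popcount((unsigned)b[i]);
  for (uint64_t idx = full * 8; idx < n; ++idx)
    if (bit_get(b, idx)) ++cnt;
  return (double)cnt;
}

// [[Rcpp::export]]
CharacterVector cpp_absent_words(RawVector bitmap, int k, std::string letters,
                                 double max_report) {
  const uint64_t A = letters.size();
  const uint64_t nwords = upow(A, k);
  const Rbyte* b = bitmap.begin();
  double nabs = (double)nwords - cpp_presence_count(bitmap, (double)nwords);
  if (nabs > max_report)
    stop("absent-word set has %.0f members, above the reporting cap of %.0f",
         nabs, max_report);
  CharacterVector out((R_xlen_t)nabs);
  R_xlen_t j = 0;
  for (uint64_t idx = 0; idx < nwords; ++idx)
    if (!bit_get(b, idx)) out[j++] = decode_word(idx, k, letters);
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_is_present(RawVector bitmap, CharacterVector words, int k,
                             std::string letters) {
  int tab[256]; make_code(letters, tab);
  const uint64_t A = letters.size();
  const Rbyte* b = bitmap.begin();
  LogicalVector out(words.size());
  for (R_xlen_t i = 0; i < words.size(); ++i) {
    const char* w = CHAR(STRING_ELT(words, i));
    uint64_t val = 0; int len = 0;
    for (const char* p = w; *p; ++p, ++len) {
      int c = tab[(unsigned char)*p];
      if (c < 0) stop("word '%s' contains a letter outside the alphabet", w);
      val = val * A + (uint64_t)c;
    }
    if (len != k) stop("word '%s' does not have length %d", w, k);
    out[i] = bit_get(b, val);
  }
  return out;
}

// Overlapping occurrence counts for a fixed target set.  In both-strand mode
// a window contributes to a target when it equals the target or its reverse
// complement; palindromic coincidences are counted once per window.
// [[Rcpp::export]]
NumericVector cpp_count_occurrences(CharacterVector seqs, CharacterVector targets,
                                    std::string letters, bool both) {
  int tab[256]; make_code(letters, tab);
  const uint64_t A = letters.size();
  int k = -1;
  std::unordered_map<uint64_t, int> idx;
  for (R_xlen_t i = 0; i < targets.size(); ++i) {
    const char* w = CHAR(STRING_ELT(targets, i));
    uint64_t val = 0; int len = 0;
    for (const char* p = w; *p; ++p, ++len) {
      int c = tab[(unsigned char)*p];
      if (c < 0) stop("target '%s' contains a letter outside the alphabet", w);
      val = val * A + (uint64_t)c;
    }
    if (k < 0) k = len;
    else if (len != k) stop("targets must all have the same length");
    idx[val] = (int)i;
  }
  if (k <= 0) return NumericVector(0);
  const uint64_t Pk1 = upow(A, k - 1);
  NumericVector counts(targets.size());
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    const char* s = CHAR(STRING_ELT(seqs, si));
    uint64_t val = 0, rcv = 0; int run = 0;
    for (const char* p = s; *p; ++p) {
      int c = tab[(unsigned char)*p];
      if (c < 0) { run = 0; val = 0; rcv = 0; continue; }
      val = (val % Pk1) * A + (uint64_t)c;
      if (both) rcv = rcv / A + (uint64_t)(3 - c) * Pk1;
      if (++run >= k) {
        auto it = idx.find(val);
        if (it != idx.end()) counts[it->second] += 1;
        if (both && rcv != val) {
          it = idx.find(rcv);
          if (it != idx.end()) counts[it->second] += 1;
        }
      }
    }
  }
  counts.names() = targets;
  return counts;
}

// forward-strand k-let counts over valid windows (shuffle conservation checks)
// [[Rcpp::export]]
List cpp_klet_counts(CharacterVector seqs, int k, std::string letters) {
  int tab[256]; make_code(letters, tab);
  const uint64_t A = letters.size();
  const uint64_t Pk1 = upow(A, k - 1);
  std::unordered_map<uint64_t, double> cnt;
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    const char* s = CHAR(STRING_ELT(seqs, si));
    uint64_t val = 0; int run = 0;
    for (const char* p = s; *p; ++p) {
      int c = tab[(unsigned char)*p];
      if (c < 0) { run = 0; val = 0; continue; }
      val = (val % Pk1) * A + (uint64_t)c;
      if (++run >= k) cnt[val] += 1;
    }
  }
  CharacterVector words(cnt.size());
  NumericVector counts(cnt.size());
  R_xlen_t j = 0;
  for (auto& kv : cnt) {
    words[j] = decode_word(kv.first, k, letters);
    counts[j] = kv.second;
    ++j;
  }
  return List::create(_["word"] = words, _["count"] = counts);
}

static void collect_absent(const std::string& edited, const Rbyte* bm, int k,
                           const int* tab, const std::string& letters,
                           bool both, std::set<std::string>& out) {
  const uint64_t A = letters.size();
  const uint64_t Pk1 = upow(A, k - 1);
  uint64_t val = 0, rcv = 0; int run = 0;
  for (char ch : edited) {
    int c = tab[(unsigned char)ch];
    if (c < 0) { run = 0; val = 0; rcv = 0; continue; }
    val = (val % Pk1) * A + (uint64_t)c;
    if (both) rcv = rcv / A + (uint64_t)(3 - c) * Pk1;
    if (++run >= k) {
      if (!bit_get(bm, val)) {
        out.insert(decode_word(val, k, letters));
        if (both && rcv != val) out.insert(decode_word(rcv, k, letters));
      }
    }
  }
}

// Exhaustive single-base edit scan: for every position, 3 substitutions
// (valid reference residues only) and 1 deletion; for every gap (1..n+1),
// 4 insertions.  Each edit is applied to a local window of radius k-1 so
// every k-window overlapping the edit is re-examined against the bitmap;
// edits materializing no absent word are suppressed.
// [[Rcpp::export]]
DataFrame cpp_scan_materializing(CharacterVector seqs, CharacterVector seqnames,
                                 RawVector bitmap, int k, std::string letters,
                                 bool both) {
  int tab[256]; make_code(letters, tab);
  const Rbyte* bm = bitmap.begin();
  const int A = (int)letters.size();
  std::vector<std::string> contig, ref, alt, mclass, words;
  std::vector<int> pos;
  auto push = [&](const std::string& nm, long p, const std::string& r,
                  const std::string& a, const char* cl,
                  const std::set<std::string>& mat) {
    std::string joined;
    for (auto& w : mat) { if (!joined.empty()) joined += ","; joined += w; }
    contig.push_back(nm); pos.push_back((int)p);
    ref.push_back(r); alt.push_back(a); mclass.push_back(cl);
    words.push_back(joined);
  };
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    std::string s = as<std::string>(seqs[si]);
    std::string nm = as<std::string>(seqnames[si]);
    const long n = (long)s.size();
    for (long p = 0; p < n; ++p) {
      const long lo = std::max(0L, p - (long)(k - 1));
      const long hi = std::min(n - 1, p + (long)(k - 1));
      if (tab[(unsigned char)s[p]] >= 0) {
        for (int a = 0; a < A; ++a) {
          char altc = letters[a];
          if (altc == s[p]) continue;
          std::string ed = s.substr(lo, hi - lo + 1);
          ed[p - lo] = altc;
          std::set<std::string> mat;
          collect_absent(ed, bm, k, tab, letters, both, mat);
          if (!mat.empty())
            push(nm, p + 1, std::string(1, s[p]), std::string(1, altc), "SUB", mat);
        }
      }
      {
        std::string ed = s.substr(lo, p - lo) +
                         s.substr(p + 1, std::min((long)(k - 1), n - 1 - p));
        std::set<std::string> mat;
        if ((long)ed.size() >= k)
          collect_absent(ed, bm, k, tab, letters, both, mat);
        if (!mat.empty())
          push(nm, p + 1, std::string(1, s[p]), "", "DEL", mat);
      }
    }
    for (long g = 0; g <= n; ++g) {  // insertion before 1-based position g+1
      const long lo = std::max(0L, g - (long)(k - 1));
      std::string left = s.substr(lo, g - lo);
      std::string right = s.substr(g, std::min((long)(k - 1), n - g));
      for (int a = 0; a < A; ++a) {
        std::string ed = left + letters[a] + right;
        std::set<std::string> mat;
        if ((long)ed.size() >= k)
          collect_absent(ed, bm, k, tab, letters, both, mat);
        if (!mat.empty())
          push(nm, g + 1, "", std::string(1, letters[a]), "INS", mat);
      }
    }
  }
  return DataFrame::create(
      _["contig"] = contig, _["pos"] = pos, _["ref"] = ref, _["alt"] = alt,
      _["mclass"] = mclass, _["words"] = words,
      _["stringsAsFactors"] = false);
}

// Deterministic Euler-path walk used by the k-let preserving shuffle:
// edges are pre-ordered per vertex by the caller (random permutation with
// the arborescence "last-exit" edge final); the walk just consumes them.
// [[Rcpp::export]]
std::string cpp_euler_walk(IntegerVector off, IntegerVector target,
                           std::string echar, int start, std::string prefix) {
  const int nv = off.size() - 1;
  std::vector<int> ptr(nv);
  for (int v = 0; v < nv; ++v) ptr[v] = off[v];
  std::string out = prefix;
  out.reserve(prefix.size() + echar.size());
  int cur = start;
  for (size_t i = 0; i < echar.size(); ++i) {
    int e = ptr[cur]++;
    out.push_back(echar[e]);
    cur = target[e];
  }
  return out;
}
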