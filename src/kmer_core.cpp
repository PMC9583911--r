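// Core k-mer machinery: canonical counting, exact-match read recruitment,
// single-k unitig compaction, and k-mer pseudo-mapping of reads onto contigs.
// k is limited to 31 so a k-mer packs into 62 bits of a uint64_t; odd k means
// no k-mer equals its own reverse complement.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <string>
#include <vector>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t revcomp_code(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return r;
}

static std::string decode_code(uint64_t x, int k) {
  std::string s((size_t)k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[(size_t)i] = BITS2BASE[x & 3ULL];
    x >>= 2;
  }
  return s;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default: break;
    }
  }
  return r;
}

static void check_k(int k) {
  if (k < 3 || k > 31 || k % 2 == 0)
    stop("k must be odd and between 3 and 31");
}

// Visit every N-free window of s as its canonical 2-bit code, with the
// 0-based start position of the window.
template <typename F>
static void for_each_canonical(const char* s, int n, int k, F f) {
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
    if (++valid >= k) f(fwd < rc ? fwd : rc, i - k + 1);
  }
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector reads, int k, int min_count) {
  check_k(k);
  if (min_count < 1) stop("min_count must be >= 1");
  std::unordered_map<uint64_t, int> cnt;
  double total_windows = 0;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    if (reads[r] == NA_STRING) continue;
    const char* s = CHAR(reads[r]);
    int n = (int)LENGTH(reads[r]);
    for_each_canonical(s, n, k, [&](uint64_t code, int) {
      ++cnt[code];
      total_windows += 1;
    });
  }
  std::vector<uint64_t> keys;
  keys.reserve(cnt.size());
  double total_retained = 0;
  for (const auto& p : cnt) {
    if (p.second >= min_count) {
      keys.push_back(p.first);
      total_retained += p.second;
    }
  }
  std::sort(keys.begin(), keys.end());
  CharacterVector kmers((R_xlen_t)keys.size());
  IntegerVector counts((R_xlen_t)keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    kmers[(R_xlen_t)i] = decode_code(keys[i], k);
    counts[(R_xlen_t)i] = cnt[keys[i]];
  }
  return List::create(_["kmer"] = kmers, _["count"] = counts,
                      _["total_retained"] = total_retained,
                      _["total_windows"] = total_windows);
}

// [[Rcpp::export]]
CharacterVector cpp_canonicalize(CharacterVector kmers) {
  CharacterVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    if (kmers[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(kmers[i]);
    bool ok = !s.empty() && s.size() <= 31;
    for (char c : s) if (base2bits(c) < 0) { ok = false; break; }
    if (!ok) { out[i] = NA_STRING; continue; }
    std::string r = revcomp_str(s);
    out[i] = (s <= r) ? s : r;
  }
  return out;
}

static std::unordered_set<uint64_t> encode_kmer_set(CharacterVector kmers, int k) {
  std::unordered_set<uint64_t> set;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    if (kmers[i] == NA_STRING) continue;
    const char* s = CHAR(kmers[i]);
    if ((int)LENGTH(kmers[i]) != k) stop("all k-mers must have length k");
    uint64_t code = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int b = base2bits(s[j]);
      if (b < 0) { ok = false; break; }
      code = (code << 2) | (uint64_t)b;
    }
    if (!ok) stop("k-mers must be over ACGT");
    uint64_t rc = revcomp_code(code, k);
    set.insert(code < rc ? code : rc);
  }
  return set;
}

// Number of *distinct* canonical query k-mers contained in each read.
// [[Rcpp::export]]
IntegerVector cpp_read_hits(CharacterVector reads, CharacterVector kmers, int k) {
  check_k(k);
  std::unordered_set<uint64_t> set = encode_kmer_set(kmers, k);
  IntegerVector hits(reads.size());
  std::vector<uint64_t> found;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    found.clear();
    if (reads[r] != NA_STRING) {
      const char* s = CHAR(reads[r]);
      int n = (int)LENGTH(reads[r]);
      for_each_canonical(s, n, k, [&](uint64_t code, int) {
        if (set.count(code)) found.push_back(code);
      });
    }
    std::sort(found.begin(), found.end());
    found.erase(std::unique(found.begin(), found.end()), found.end());
    hits[r] = (int)found.size();
  }
  return hits;
}

// ---- unitig assembler -------------------------------------------------------

struct DbgCtx {
  const std::unordered_set<uint64_t>* S;
  int k;
  uint64_t mask;
  int shift;
};

static inline uint64_t canon_of(uint64_t x, const DbgCtx& g) {
  uint64_t rc = revcomp_code(x, g.k);
  return x < rc ? x : rc;
}

// Unique forward extension of oriented k-mer x, or return false.
static bool unique_successor(uint64_t x, const DbgCtx& g, uint64_t& y_out) {
  int n = 0;
  uint64_t y = 0;
  for (uint64_t c = 0; c < 4; ++c) {
    uint64_t cand = ((x << 2) & g.mask) | c;
    if (g.S->count(canon_of(cand, g))) { ++n; y = cand; }
  }
  if (n != 1) return false;
  // the successor must in turn have x as its only predecessor
  int np = 0;
  for (uint64_t c = 0; c < 4; ++c) {
    uint64_t pred = (y >> 2) | (c << g.shift);
    if (g.S->count(canon_of(pred, g))) ++np;
  }
  if (np != 1) return false;
  y_out = y;
  return true;
}

static std::string extend_right(uint64_t start, const DbgCtx& g,
                                std::unordered_set<uint64_t>& visited) {
  std::string seq = decode_code(start, g.k);
  uint64_t cur = start;
  for (;;) {
    uint64_t y;
    if (!unique_successor(cur, g, y)) break;
    uint64_t cy = canon_of(y, g);
    if (visited.count(cy)) break;
    visited.insert(cy);
    seq.push_back(BITS2BASE[y & 3ULL]);
    cur = y;
  }
  return seq;
}

// [[Rcpp::export]]
List cpp_assemble_unitigs(CharacterVector reads, int k, int cov_floor) {
  check_k(k);
  if (cov_floor < 1) stop("coverage floor must be >= 1");
  std::unordered_map<uint64_t, int> cnt;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    if (reads[r] == NA_STRING) continue;
    for_each_canonical(CHAR(reads[r]), (int)LENGTH(reads[r]), k,
                       [&](uint64_t code, int) { ++cnt[code]; });
  }
  std::vector<uint64_t> keys;
  std::unordered_set<uint64_t> S;
  for (const auto& p : cnt)
    if (p.second >= cov_floor) keys.push_back(p.first);
  std::sort(keys.begin(), keys.end());
  S.insert(keys.begin(), keys.end());

  DbgCtx g{&S, k, (1ULL << (2 * k)) - 1, 2 * (k - 1)};
  std::unordered_set<uint64_t> visited;
  std::vector<std::string> unitigs;
  for (uint64_t s0 : keys) {
    if (visited.count(s0)) continue;
    visited.insert(s0);
    std::string right = extend_right(s0, g, visited);
    std::string left = extend_right(revcomp_code(s0, k), g, visited);
    // left, reverse-complemented, ends with decode(s0); splice the two halves
    std::string seq = revcomp_str(left) + right.substr((size_t)k);
    std::string rc = revcomp_str(seq);
    unitigs.push_back(seq <= rc ? seq : rc);
  }
  CharacterVector out((R_xlen_t)unitigs.size());
  for (size_t i = 0; i < unitigs.size(); ++i) out[(R_xlen_t)i] = unitigs[i];
  return List::create(_["unitig"] = out, _["n_kmers_kept"] = (double)keys.size());
}

// ---- k-mer pseudo-mapping ---------------------------------------------------

// A read maps to a contig when at least `min_shared` of its distinct canonical
// k-mers occur in the contig; min_shared <= 0 demands *all* of them (the k-mer
// analogue of end-to-end alignment with zero mismatches). Ties between contigs
// go to the smallest contig index. Depth is added over the matched span.
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector contigs, int k,
                   int min_shared) {
  check_k(k);
  int nc = (int)contigs.size();
  if (nc == 0) stop("no contigs supplied");
  // code -> list of (contig, first position)
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> idx;
  std::vector<int> clen(nc);
  for (int i = 0; i < nc; ++i) {
    if (contigs[i] == NA_STRING) stop("contig sequence is NA");
    clen[i] = (int)LENGTH(contigs[i]);
    for_each_canonical(CHAR(contigs[i]), clen[i], k, [&](uint64_t code, int pos) {
      auto& v = idx[code];
      if (v.empty() || v.back().first != i) v.emplace_back(i, pos);
    });
  }
  R_xlen_t nr = reads.size();
  IntegerVector assignment(nr, NA_INTEGER);
  IntegerVector counts(nc, 0);
  std::vector<std::vector<double>> depth((size_t)nc);
  for (int i = 0; i < nc; ++i) depth[(size_t)i].assign((size_t)clen[i], 0.0);

  std::vector<int> shared((size_t)nc, 0), lo((size_t)nc, 0), hi((size_t)nc, 0);
  std::vector<int> touched;
  std::vector<uint64_t> codes;
  for (R_xlen_t r = 0; r < nr; ++r) {
    if (reads[r] == NA_STRING) continue;
    codes.clear();
    for_each_canonical(CHAR(reads[r]), (int)LENGTH(reads[r]), k,
                       [&](uint64_t code, int) { codes.push_back(code); });
    std::sort(codes.begin(), codes.end());
    codes.erase(std::unique(codes.begin(), codes.end()), codes.end());
    if (codes.empty()) continue;
    touched.clear();
    for (uint64_t code : codes) {
      auto it = idx.find(code);
      if (it == idx.end()) continue;
      for (const auto& cp : it->second) {
        int c = cp.first;
        if (shared[(size_t)c] == 0) {
          touched.push_back(c);
          lo[(size_t)c] = cp.second;
          hi[(size_t)c] = cp.second;
        } else {
          lo[(size_t)c] = std::min(lo[(size_t)c], cp.second);
          hi[(size_t)c] = std::max(hi[(size_t)c], cp.second);
        }
        ++shared[(size_t)c];
      }
    }
    int need = (min_shared <= 0) ? (int)codes.size() : min_shared;
    int best = -1, best_shared = 0;
    for (int c : touched) {
      int sh = shared[(size_t)c];
      if (sh < need) continue;
      if (sh > best_shared || (sh == best_shared && (best < 0 || c < best))) {
        best = c;
        best_shared = sh;
      }
    }
    if (best >= 0) {
      assignment[r] = best + 1;
      ++counts[best];
      int from = lo[(size_t)best];
      int to = std::min(hi[(size_t)best] + k, clen[best]);
      for (int p = from; p < to; ++p) depth[(size_t)best][(size_t)p] += 1.0;
    }
    for (int c : touched) shared[(size_t)c] = 0;
  }
  List cov(nc);
  for (int i = 0; i < nc; ++i) cov[i] = NumericVector(depth[(size_t)i].begin(),
                                                      depth[(size_t)i].end());
  return List::create(_["assignment"] = assignment, _["counts"] = counts,
                      _["coverage"] = cov);
}

// Substitution error injection for the read simulator: replace the base at
// pos[i] (1-based) of reads[idx[i]] by (base + offset) mod 4, offset in 1..3.
// [[Rcpp::export]]
CharacterVector cpp_apply_subs(CharacterVector reads, IntegerVector idx,
                               IntegerVector pos, IntegerVector offset) {
  if (idx.size() != pos.size() || idx.size() != offset.size())
    stop("idx, pos and offset must have equal length");
  std::vector<std::string> out((size_t)reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) out[(size_t)i] = as<std::string>(reads[i]);
  for (R_xlen_t i = 0; i < idx.size(); ++i) {
    std::string& s = out[(size_t)(idx[i] - 1)];
    int p = pos[i] - 1;
    if (p < 0 || p >= (int)s.size()) stop("substitution position out of range");
    int b = base2bits(s[(size_t)p]);
    if (b < 0) continue;
    s[(size_t)p] = BITS2BASE[(b + offset[i]) & 3];
  }
  CharacterVector res(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) res[i] = out[(size_t)i];
  return res;
}
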