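// Low-level kernels: canonical k-mer hashing, exact-seed ungapped read
// alignment, split-anchored single-indel alignment, and banded global
// alignment identity. All randomness-free and deterministic; 64-bit hashes
// are masked to 53 bits so they round-trip exactly through R doubles.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

static inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// 53-bit mask: largest integer range exactly representable in a double.
static const uint64_t HASH53 = (1ULL << 53) - 1;

// Walk all canonical k-mer codes of seq, invoking fn(position, canonical_code)
// for every window free of non-ACGT characters.
template <typename F>
static void for_each_canonical(const char* seq, size_t n, int k, F fn) {
  if (k < 1 || (size_t)k > n || k > 32) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  for (size_t i = 0; i < n; ++i) {
    int c = base2code(seq[i]);
    if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) {
      uint64_t canon = fwd < rc ? fwd : rc;
      fn(i + 1 - k, canon);
    }
  }
}

// [[Rcpp::export(name = ".canonical_kmers_cpp")]]
CharacterVector canonical_kmers_cpp(std::string seq, int k) {
  std::vector<std::string> out;
  for_each_canonical(seq.c_str(), seq.size(), k,
                     [&](size_t, uint64_t canon) {
    std::string km(k, 'A');
    for (int j = k - 1; j >= 0; --j) {
      km[j] = CODE2BASE[canon & 3];
      canon >>= 2;
    }
    out.push_back(km);
  });
  return wrap(out);
}

// Sorted unique 53-bit hash values of all canonical k-mers in seqs.
// [[Rcpp::export(name = ".kmer_hashes_cpp")]]
NumericVector kmer_hashes_cpp(CharacterVector seqs, int k, double seed) {
  if (k < 1 || k > 32) stop("k must be in [1, 32]");
  uint64_t seed_mix = splitmix64((uint64_t)seed);
  std::vector<uint64_t> hashes;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* p = CHAR(STRING_ELT(seqs, s));
    size_t n = std::strlen(p);
    for_each_canonical(p, n, k, [&](size_t, uint64_t canon) {
      hashes.push_back(splitmix64(canon ^ seed_mix) & HASH53);
    });
  }
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  NumericVector out(hashes.size());
  for (size_t i = 0; i < hashes.size(); ++i) out[i] = (double)hashes[i];
  return out;
}

// Count of valid (N-free) k-mer windows, for sketch invariants.
// [[Rcpp::export(name = ".count_kmer_windows_cpp")]]
double count_kmer_windows_cpp(CharacterVector seqs, int k) {
  double total = 0;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* p = CHAR(STRING_ELT(seqs, s));
    size_t n = std::strlen(p);
    for_each_canonical(p, n, k, [&](size_t, uint64_t) { total += 1; });
  }
  return total;
}

struct SeedIndex {
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> map;
  int k;
};

static void index_targets(const CharacterVector& targets, int seed_len,
                          SeedIndex& idx) {
  idx.k = seed_len;
  for (R_xlen_t t = 0; t < targets.size(); ++t) {
    const char* p = CHAR(STRING_ELT(targets, t));
    size_t n = std::strlen(p);
    const uint64_t mask =
        (seed_len == 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);
    uint64_t code = 0;
    int run = 0;
    for (size_t i = 0; i < n; ++i) {
      int c = base2code(p[i]);
      if (c < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)c) & mask;
      if (++run >= seed_len)
        idx.map[code].push_back({(int)t, (int)(i + 1 - seed_len)});
    }
  }
}

static inline int count_matches(const char* read, int rlen, const char* tgt,
                                int off) {
  int m = 0;
  for (int i = 0; i < rlen; ++i)
    if (std::toupper(read[i]) == std::toupper(tgt[off + i])) ++m;
  return m;
}

// Seed-and-extend ungapped mapping of reads against one or more targets.
// Best alignment per (read, target) with identity >= min_identity; ties
// resolved toward the leftmost coordinate, then '+' strand. Edits encode
// mismatches as "targetpos:readbase" (0-based), comma separated.
// [[Rcpp::export(name = ".map_reads_cpp")]]
List map_reads_cpp(CharacterVector reads, CharacterVector targets,
                   double min_identity, int seed_len) {
  if (seed_len < 1 || seed_len > 32) stop("seed_len must be in [1, 32]");
  SeedIndex idx;
  index_targets(targets, seed_len, idx);

  std::vector<const char*> tseq(targets.size());
  std::vector<int> tlen(targets.size());
  for (R_xlen_t t = 0; t < targets.size(); ++t) {
    tseq[t] = CHAR(STRING_ELT(targets, t));
    tlen[t] = (int)std::strlen(tseq[t]);
  }

  std::vector<int> o_read, o_target, o_start, o_matches, o_len;
  std::vector<int> o_strand; // 0 = '+', 1 = '-'
  std::vector<std::string> o_edits;

  const uint64_t mask =
      (seed_len == 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);

  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string fwd = CHAR(STRING_ELT(reads, r));
    int rlen = (int)fwd.size();
    if (rlen < seed_len) continue;
    std::string rev = revcomp(fwd);
    // candidates: (target, offset, strand)
    std::vector<std::array<int, 3>> cand;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& rs = strand == 0 ? fwd : rev;
      uint64_t code = 0;
      int run = 0;
      for (int i = 0; i < rlen; ++i) {
        int c = base2code(rs[i]);
        if (c < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t)c) & mask;
        if (++run >= seed_len) {
          auto it = idx.map.find(code);
          if (it == idx.map.end()) continue;
          int p = i + 1 - seed_len;
          for (const auto& hit : it->second) {
            int off = hit.second - p;
            if (off >= 0 && off + rlen <= tlen[hit.first])
              cand.push_back({hit.first, off, strand});
          }
        }
      }
    }
    if (cand.empty()) continue;
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

    // best per target: identity desc, offset asc, '+' before '-'
    int cur_t = -1, best_m = -1, best_off = 0, best_strand = 0;
    auto flush = [&](int t) {
      if (t < 0 || best_m < 0) return;
      double ident = (double)best_m / rlen;
      if (ident + 1e-12 < min_identity) return;
      const std::string& rs = best_strand == 0 ? fwd : rev;
      std::string ed;
      for (int i = 0; i < rlen; ++i) {
        if (std::toupper(rs[i]) != std::toupper(tseq[t][best_off + i])) {
          if (!ed.empty()) ed += ',';
          ed += std::to_string(best_off + i);
          ed += ':';
          ed += (char)std::toupper(rs[i]);
        }
      }
      o_read.push_back((int)r + 1);
      o_target.push_back(t + 1);
      o_start.push_back(best_off);
      o_strand.push_back(best_strand);
      o_matches.push_back(best_m);
      o_len.push_back(rlen);
      o_edits.push_back(ed);
    };
    for (const auto& c : cand) {
      if (c[0] != cur_t) {
        flush(cur_t);
        cur_t = c[0];
        best_m = -1;
      }
      const std::string& rs = c[2] == 0 ? fwd : rev;
      int m = count_matches(rs.c_str(), rlen, tseq[c[0]], c[1]);
      bool better = m > best_m ||
        (m == best_m && (c[1] < best_off ||
                         (c[1] == best_off && c[2] < best_strand)));
      if (better) { best_m = m; best_off = c[1]; best_strand = c[2]; }
    }
    flush(cur_t);
  }

  return List::create(
      _["read"] = wrap(o_read), _["target"] = wrap(o_target),
      _["start"] = wrap(o_start), _["strand"] = wrap(o_strand),
      _["matches"] = wrap(o_matches), _["len"] = wrap(o_len),
      _["edits"] = wrap(o_edits));
}

static void find_occurrences(const std::string& needle,
                             const char* hay, int hlen,
                             std::vector<int>& out, int cap) {
  int nl = (int)needle.size();
  for (int i = 0; i + nl <= hlen && (int)out.size() < cap; ++i) {
    if (std::strncmp(hay + i, needle.c_str(), nl) == 0) out.push_back(i);
  }
}

// Split-anchored alignment detecting one indel of <= max_indel bases between
// read and target. Anchors the first and last seed_len bases exactly; the
// offset difference is the indel size; the breakpoint maximizes matches.
// indel_len > 0: target bases [left_start+break, +indel_len) absent from read
// (a deletion in the sample). indel_len < 0: the read carries |indel_len|
// extra bases inserted after target position left_start+break-1.
// [[Rcpp::export(name = ".indel_align_cpp")]]
List indel_align_cpp(std::string read, std::string target, int seed_len,
                     int max_indel, double min_identity) {
  int rlen = (int)read.size();
  int tlen = (int)target.size();
  List fail = List::create(_["found"] = false);
  if (rlen < 2 * seed_len) return fail;

  int best_total = -1, best_oL = 0, best_b = 0, best_d = 0, best_strand = 0;
  for (int strand = 0; strand < 2; ++strand) {
    std::string rs = strand == 0 ? read : revcomp(read);
    std::vector<int> pre, suf;
    find_occurrences(rs.substr(0, seed_len), target.c_str(), tlen, pre, 32);
    find_occurrences(rs.substr(rlen - seed_len), target.c_str(), tlen, suf, 32);
    for (int oL : pre) {
      for (int sp : suf) {
        int oR = sp - (rlen - seed_len);
        int d = oR - oL;
        if (d == 0 || d > max_indel || -d > max_indel) continue;
        if (oL < 0 || oR < 0 || oR + rlen > tlen || oL + rlen > tlen + std::max(d, 0))
          continue;
        // prefix matches at offset oL, cumulative
        std::vector<int> pm(rlen + 1, 0);
        for (int i = 0; i < rlen; ++i) {
          int tp = oL + i;
          pm[i + 1] = pm[i] +
            (tp < tlen && std::toupper(rs[i]) == std::toupper(target[tp]) ? 1 : 0);
        }
        // suffix matches at offset oR, cumulative from the right
        std::vector<int> sm(rlen + 2, 0);
        for (int i = rlen - 1; i >= 0; --i) {
          int tp = oR + i;
          sm[i] = sm[i + 1] +
            (tp >= 0 && tp < tlen &&
             std::toupper(rs[i]) == std::toupper(target[tp]) ? 1 : 0);
        }
        int ins = d < 0 ? -d : 0;
        for (int b = seed_len; b <= rlen - seed_len - ins; ++b) {
          int total = pm[b] + sm[b + ins];
          if (total > best_total) {
            best_total = total; best_oL = oL; best_b = b; best_d = d;
            best_strand = strand;
          }
        }
      }
    }
  }
  if (best_total < 0) return fail;
  double ident = (double)best_total / rlen;
  if (ident + 1e-12 < min_identity) return fail;

  std::string rs = best_strand == 0 ? read : revcomp(read);
  int ins = best_d < 0 ? -best_d : 0;
  int oR = best_oL + best_d;
  std::string edl, edr;
  for (int i = 0; i < best_b; ++i) {
    if (std::toupper(rs[i]) != std::toupper(target[best_oL + i])) {
      if (!edl.empty()) edl += ',';
      edl += std::to_string(best_oL + i);
      edl += ':';
      edl += (char)std::toupper(rs[i]);
    }
  }
  for (int i = best_b + ins; i < rlen; ++i) {
    if (std::toupper(rs[i]) != std::toupper(target[oR + i])) {
      if (!edr.empty()) edr += ',';
      edr += std::to_string(oR + i);
      edr += ':';
      edr += (char)std::toupper(rs[i]);
    }
  }
  std::string ins_seq = ins > 0 ? rs.substr(best_b, ins) : std::string();
  for (auto& ch : ins_seq) ch = (char)std::toupper(ch);
  return List::create(
      _["found"] = true, _["strand"] = best_strand == 0 ? "+" : "-",
      _["left_start"] = best_oL, _["breakpoint"] = best_b,
      _["indel_len"] = best_d, _["ins_seq"] = ins_seq,
      _["matches"] = best_total,
      _["left_interval"] = IntegerVector::create(best_oL, best_oL + best_b),
      _["right_interval"] =
          IntegerVector::create(oR + best_b + ins, oR + rlen),
      _["edits_left"] = edl, _["edits_right"] = edr);
}

// Identity = matches / alignment columns on the minimum-edit global alignment
// path, computed inside a diagonal band (5% of the longer length by default,
// widened by the length difference; floor 10).
// [[Rcpp::export(name = ".banded_identity_cpp")]]
double banded_identity_cpp(std::string a, std::string b,
                           double band_frac = 0.05) {
  int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) return 0.0;
  int band = std::max(10, (int)std::ceil(band_frac * std::max(n, m)));
  band += std::abs(n - m);
  const int INF = 1 << 28;
  std::vector<int> dist((size_t)(n + 1) * (m + 1), INF);
  auto D = [&](int i, int j) -> int& { return dist[(size_t)i * (m + 1) + j]; };
  for (int j = 0; j <= std::min(m, band); ++j) D(0, j) = j;
  for (int i = 0; i <= std::min(n, band); ++i) D(i, 0) = i;
  for (int i = 1; i <= n; ++i) {
    int lo = std::max(1, i - band), hi = std::min(m, i + band);
    for (int j = lo; j <= hi; ++j) {
      int sub = D(i - 1, j - 1) == INF ? INF :
        D(i - 1, j - 1) + (std::toupper(a[i - 1]) == std::toupper(b[j - 1]) ? 0 : 1);
      int del = D(i - 1, j) == INF ? INF : D(i - 1, j) + 1;
      int ins = D(i, j - 1) == INF ? INF : D(i, j - 1) + 1;
      D(i, j) = std::min(sub, std::min(del, ins));
    }
  }
  if (D(n, m) >= INF) return 0.0;
  // traceback (diagonal preferred) counting matches and columns
  int i = n, j = m, matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && D(i - 1, j - 1) != INF &&
        D(i, j) == D(i - 1, j - 1) +
            (std::toupper(a[i - 1]) == std::toupper(b[j - 1]) ? 0 : 1)) {
      if (std::toupper(a[i - 1]) == std::toupper(b[j - 1])) ++matches;
      --i; --j;
    } else if (i > 0 && D(i - 1, j) != INF && D(i, j) == D(i - 1, j) + 1) {
      --i;
    } else {
      --j;
    }
    ++cols;
  }
  return (double)matches / cols;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    out[i] = revcomp(std::string(CHAR(STRING_ELT(seqs, i))));
  }
  return out;
}

// Inject i.i.d. substitution errors; err_pos/err_base are per-read flattened
// (1-based positions, replacement base indices 0..2 meaning "pick among the
// three alternatives"). Kept in C++ only for speed of the read simulator.
// [[Rcpp::export(name = ".apply_substitutions_cpp")]]
CharacterVector apply_substitutions_cpp(CharacterVector seqs, List positions,
                                        List alts) {
  CharacterVector out(seqs.size());
  const char* bases = "ACGT";
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = CHAR(STRING_ELT(seqs, i));
    IntegerVector pos = positions[i];
    IntegerVector alt = alts[i];
    for (int j = 0; j < pos.size(); ++j) {
      int p = pos[j] - 1;
      if (p < 0 || p >= (int)s.size()) continue;
      int cur = base2code(s[p]);
      if (cur < 0) continue;
      int pick = alt[j] % 3;
      int nb = (cur + 1 + pick) % 4;
      s[p] = bases[nb];
    }
    out[i] = s;
  }
  return out;
}
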