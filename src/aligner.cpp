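// Pigeonhole seed-and-verify short read aligner.
//
// A read of length L aligned with at most m mismatches must contain at
// least one exact segment when the read is partitioned into m + 1
// non-overlapping segments of length k = floor(L / (m + 1)).  We index
// every k-mer of every reference, look up each read segment, and verify
// candidate placements by direct Hamming comparison.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct SeedIndex {
  int k;
  std::vector<std::string> seqs;
  std::vector<std::string> names;
  std::unordered_map<std::uint64_t, std::vector<std::pair<int, int> > > table;
  std::uint64_t n_positions;
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k) {
  if (k < 1 || k > 31) stop("seed length k must be in [1, 31]");
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  idx->n_positions = 0;
  const std::uint64_t mask =
      (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    idx->seqs.push_back(as<std::string>(seqs[i]));
    idx->names.push_back(as<std::string>(names[i]));
  }
  for (int r = 0; r < (int)idx->seqs.size(); ++r) {
    const std::string& s = idx->seqs[r];
    if ((int)s.size() < k) continue;
    std::uint64_t key = 0;
    int valid = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      int c = base_code(s[p]);
      if (c < 0) {  // ambiguous base breaks the rolling window
        valid = 0;
        key = 0;
        continue;
      }
      key = ((key << 2) | (std::uint64_t)c) & mask;
      ++valid;
      if (valid >= k) {
        idx->table[key].push_back(std::make_pair(r, p - k + 1));
        idx->n_positions += 1;
      }
    }
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  return List::create(
      _["k"] = idx->k,
      _["n_references"] = (int)idx->seqs.size(),
      _["n_positions"] = (double)idx->n_positions,
      _["n_distinct_kmers"] = (double)idx->table.size());
}

// [[Rcpp::export]]
DataFrame cpp_query_kmer(SEXP xp, std::string kmer) {
  XPtr<SeedIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("query length must equal seed length k");
  std::uint64_t key = 0;
  for (size_t i = 0; i < kmer.size(); ++i) {
    int c = base_code(kmer[i]);
    if (c < 0)
      return DataFrame::create(_["ref"] = IntegerVector(0),
                               _["offset"] = IntegerVector(0));
    key = (key << 2) | (std::uint64_t)c;
  }
  std::vector<int> refs, offs;
  std::unordered_map<std::uint64_t,
                     std::vector<std::pair<int, int> > >::const_iterator it =
      idx->table.find(key);
  if (it != idx->table.end()) {
    for (size_t j = 0; j < it->second.size(); ++j) {
      refs.push_back(it->second[j].first + 1);  // 1-based ref index for R
      offs.push_back(it->second[j].second);     // 0-based offset
    }
  }
  return DataFrame::create(_["ref"] = wrap(refs), _["offset"] = wrap(offs));
}

struct Hit {
  int read;
  int ref;
  int offset;
  int mm;
};

static bool hit_less(const Hit& a, const Hit& b) {
  if (a.read != b.read) return a.read < b.read;
  if (a.ref != b.ref) return a.ref < b.ref;
  return a.offset < b.offset;
}

// [[Rcpp::export]]
DataFrame cpp_align(SEXP xp, CharacterVector reads, int max_mm) {
  XPtr<SeedIndex> idx(xp);
  const int k = idx->k;
  std::vector<Hit> hits;
  std::vector<int> seg_offsets;
  std::unordered_set<std::uint64_t> seen;
  const std::uint64_t mask =
      (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;

  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const std::string read = as<std::string>(reads[i]);
    const int L = (int)read.size();
    if (L < k) continue;

    // segment anchors: multiples of k plus one flush with the read end
    seg_offsets.clear();
    for (int o = 0; o + k <= L; o += k) seg_offsets.push_back(o);
    if (seg_offsets.empty() || seg_offsets.back() != L - k)
      seg_offsets.push_back(L - k);

    seen.clear();
    for (size_t si = 0; si < seg_offsets.size(); ++si) {
      const int so = seg_offsets[si];
      std::uint64_t key = 0;
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        int c = base_code(read[so + j]);
        if (c < 0) { ok = false; break; }
        key = ((key << 2) | (std::uint64_t)c) & mask;
      }
      if (!ok) continue;
      std::unordered_map<std::uint64_t,
                         std::vector<std::pair<int, int> > >::const_iterator
          it = idx->table.find(key);
      if (it == idx->table.end()) continue;
      const std::vector<std::pair<int, int> >& posts = it->second;
      for (size_t pj = 0; pj < posts.size(); ++pj) {
        const int r = posts[pj].first;
        const int cand = posts[pj].second - so;  // candidate read offset
        if (cand < 0) continue;
        const std::string& ref = idx->seqs[r];
        if (cand + L > (int)ref.size()) continue;
        const std::uint64_t ckey =
            ((std::uint64_t)r << 33) | (std::uint64_t)(cand + 1);
        if (!seen.insert(ckey).second) continue;  // already verified
        int mm = 0;
        for (int j = 0; j < L; ++j) {
          char rc = read[j], gc = ref[cand + j];
          int a = base_code(rc), b = base_code(gc);
          // ambiguous bases never match anything
          if (a < 0 || b < 0 || a != b) {
            if (++mm > max_mm) break;
          }
        }
        if (mm <= max_mm) {
          Hit h;
          h.read = (int)i + 1;
          h.ref = r + 1;
          h.offset = cand;
          h.mm = mm;
          hits.push_back(h);
        }
      }
    }
  }

  std::sort(hits.begin(), hits.end(), hit_less);
  const size_t n = hits.size();
  IntegerVector rd(n), rf(n), of(n), mmv(n);
  for (size_t i = 0; i < n; ++i) {
    rd[i] = hits[i].read;
    rf[i] = hits[i].ref;
    of[i] = hits[i].offset;
    mmv[i] = hits[i].mm;
  }
  return DataFrame::create(_["read"] = rd, _["ref"] = rf,
                           _["offset"] = of, _["mismatches"] = mmv);
}

// [[Rcpp::export]]
IntegerVector cpp_count_n(CharacterVector reads) {
  IntegerVector out(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int n = 0;
    for (; *s; ++s)
      if (base_code(*s) < 0) ++n;
    out[i] = n;
  }
  return out;
}
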