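#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Exact seed-and-verify evaluation of the frame-match criterion: a read
// matches when some ungapped placement against the ORF (this orientation
// only) has at least `thr` identical bases, overhanging positions counting
// as mismatches.  With m = len - thr allowed mismatches, any qualifying
// placement contains an exact run of >= ceil(thr / (m + 1)) bases
// (pigeonhole), so a k-mer seed index with k <= that bound finds every
// qualifying diagonal: the result equals brute force over all placements.

static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static int threshold_for(int len, int min_identity, int identity_window) {
  if (len >= identity_window) return min_identity;
  // shorter (trimmed) reads: scale the identity requirement proportionally
  return (int)std::ceil((double)min_identity * len / identity_window);
}

// Count identical bases for a placement where read position i aligns ORF
// position diag + i; out-of-range positions mismatch.
static int diag_matches(const std::string& rd, const std::string& orf,
                        long diag) {
  long L = (long)rd.size(), M = (long)orf.size();
  long i0 = std::max(0L, -diag);
  long i1 = std::min(L, M - diag);
  int n = 0;
  for (long i = i0; i < i1; ++i)
    if (rd[(size_t)i] == orf[(size_t)(diag + i)]) ++n;
  return n;
}

// [[Rcpp::export(name = ".cpp_frame_matches")]]
LogicalVector cpp_frame_matches(CharacterVector reads, std::string orf,
                                int min_identity, int identity_window) {
  int n = reads.size();
  LogicalVector out(n);
  if (n == 0) return out;

  // smallest guaranteed seed length over the read lengths present
  int k = identity_window;
  for (int r = 0; r < n; ++r) {
    int len = LENGTH(STRING_ELT(reads, r));
    int thr = threshold_for(len, min_identity, identity_window);
    int m = len - thr;
    int kr = (m >= 0) ? (thr + m) / (m + 1) : len; // ceil(thr/(m+1))
    if (kr < 1) kr = 1;
    if (kr < k) k = kr;
  }
  if (k > 31) k = 31;

  long M = (long)orf.size();
  if (M < k) {
    // degenerate: brute-force every diagonal
    for (int r = 0; r < n; ++r) {
      std::string rd = as<std::string>(reads[r]);
      int thr = threshold_for((int)rd.size(), min_identity, identity_window);
      bool hit = false;
      for (long d = -(long)rd.size() + 1; d < M && !hit; ++d)
        if (diag_matches(rd, orf, d) >= thr) hit = true;
      out[r] = hit;
    }
    return out;
  }

  // index all ORF k-mers
  std::unordered_map<uint64_t, std::vector<int32_t> > idx;
  idx.reserve((size_t)M * 2);
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t h = 0;
  int run = 0;
  for (long j = 0; j < M; ++j) {
    int b = base2bit(orf[(size_t)j]);
    if (b < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)b) & mask;
    if (++run >= k) idx[h].push_back((int32_t)(j - k + 1));
  }

  std::vector<long> diags;
  for (int r = 0; r < n; ++r) {
    std::string rd = as<std::string>(reads[r]);
    long L = (long)rd.size();
    int thr = threshold_for((int)L, min_identity, identity_window);
    if (L < k) { out[r] = false; continue; }
    diags.clear();
    h = 0; run = 0;
    for (long i = 0; i < L; ++i) {
      int b = base2bit(rd[(size_t)i]);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        auto it = idx.find(h);
        if (it != idx.end()) {
          long ri = i - k + 1;
          for (int32_t pj : it->second) diags.push_back((long)pj - ri);
        }
      }
    }
    std::sort(diags.begin(), diags.end());
    diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
    bool hit = false;
    for (long d : diags) {
      if (diag_matches(rd, orf, d) >= thr) { hit = true; break; }
    }
    out[r] = hit;
  }
  return out;
}
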