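#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int enc(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

static inline char cpl(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  }
  return 'N';
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) c = cpl(c);
  return out;
}

// mismatch count with early exit once the cap is exceeded; a position
// matches only when both characters are equal AND a concrete base (N never
// matches anything, including N)
static inline int count_mismatch(const char* r, const char* s, int L, int cap) {
  int mm = 0;
  for (int i = 0; i < L; ++i) {
    char a = r[i];
    if (a != s[i] || enc(a) < 0) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

struct Placement { int pos; int strand; };  // strand: +1 fwd, -1 rev

static void record(std::vector<int>& tr, std::vector<int>& tp,
                   std::vector<int>& ts, int read1,
                   std::vector<Placement>& bests) {
  std::sort(bests.begin(), bests.end(), [](const Placement& a, const Placement& b) {
    return a.pos != b.pos ? a.pos < b.pos : a.strand > b.strand;
  });
  for (auto& p : bests) {
    tr.push_back(read1);
    tp.push_back(p.pos);
    ts.push_back(p.strand);
  }
}

// Pigeonhole-seeded ungapped mapper against one contig. Each read is split
// into max_mismatch+1 chunks; any placement with <= max_mismatch mismatches
// has at least one exactly-matching chunk, whose first seed_len bases index
// into a hash of reference seed_len-mers. Candidates are verified by full
// comparison, so results are identical to exhaustive scanning.
// [[Rcpp::export]]
List cpp_map_to_ref(CharacterVector reads, std::string ref, int max_mismatch,
                    int seed_len) {
  const int N = (int)ref.size();
  std::unordered_map<uint64_t, std::vector<int>> index;
  if (seed_len >= 1 && seed_len <= 31 && seed_len <= N) {
    index.reserve((size_t)N * 2);
    const uint64_t mask = (1ULL << (2 * seed_len)) - 1;
    uint64_t key = 0;
    int valid = 0;
    for (int i = 0; i < N; ++i) {
      int e = enc(ref[i]);
      if (e < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)e) & mask;
      ++valid;
      if (valid >= seed_len) index[key].push_back(i - seed_len + 1);
    }
  }

  const int n = reads.size();
  IntegerVector best_mm(n, NA_INTEGER), n_best(n, 0);
  LogicalVector too_long(n, false);
  std::vector<int> tie_read, tie_pos, tie_strand;

  for (int r = 0; r < n; ++r) {
    std::string rd = as<std::string>(reads[r]);
    const int L = (int)rd.size();
    if (L == 0) continue;
    if (L > N) { too_long[r] = true; continue; }
    std::string rdrc = revcomp_str(rd);
    int best = max_mismatch + 1;
    std::vector<Placement> bests;
    std::vector<int> seen;  // strand*(N-L+1)+start, linear dedup (few candidates)
    const int nchunk = max_mismatch + 1;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = (strand == 0) ? rd : rdrc;
      for (int c = 0; c < nchunk; ++c) {
        int cs = (int)(((long long)c * L) / nchunk);
        if (cs + seed_len > L) continue;
        uint64_t key = 0;
        bool ok = true;
        for (int j = 0; j < seed_len; ++j) {
          int e = enc(q[cs + j]);
          if (e < 0) { ok = false; break; }
          key = (key << 2) | (uint64_t)e;
        }
        if (!ok) continue;
        auto it = index.find(key);
        if (it == index.end()) continue;
        for (int p : it->second) {
          int start = p - cs;
          if (start < 0 || start + L > N) continue;
          int si = strand * (N - L + 1) + start;
          if (std::find(seen.begin(), seen.end(), si) != seen.end()) continue;
          seen.push_back(si);
          int mm = count_mismatch(q.c_str(), ref.c_str() + start, L, max_mismatch);
          if (mm > max_mismatch) continue;
          if (mm < best) { best = mm; bests.clear(); }
          if (mm == best) bests.push_back({start, strand == 0 ? 1 : -1});
        }
      }
    }
    if (!bests.empty()) {
      best_mm[r] = best;
      n_best[r] = (int)bests.size();
      record(tie_read, tie_pos, tie_strand, r + 1, bests);
    }
  }
  return List::create(_["best_mm"] = best_mm, _["n_best"] = n_best,
                      _["too_long"] = too_long, _["tie_read"] = wrap(tie_read),
                      _["tie_pos"] = wrap(tie_pos),
                      _["tie_strand"] = wrap(tie_strand));
}

// Exhaustive all-offsets, both-strands scan; independent oracle for the
// seeded mapper (identical output layout).
// [[Rcpp::export]]
List cpp_bruteforce_map(CharacterVector reads, std::string ref,
                        int max_mismatch) {
  const int N = (int)ref.size();
  const int n = reads.size();
  IntegerVector best_mm(n, NA_INTEGER), n_best(n, 0);
  LogicalVector too_long(n, false);
  std::vector<int> tie_read, tie_pos, tie_strand;
  for (int r = 0; r < n; ++r) {
    std::string rd = as<std::string>(reads[r]);
    const int L = (int)rd.size();
    if (L == 0) continue;
    if (L > N) { too_long[r] = true; continue; }
    std::string rdrc = revcomp_str(rd);
    int best = max_mismatch + 1;
    std::vector<Placement> bests;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = (strand == 0) ? rd : rdrc;
      for (int start = 0; start + L <= N; ++start) {
        int mm = count_mismatch(q.c_str(), ref.c_str() + start, L, max_mismatch);
        if (mm > max_mismatch) continue;
        if (mm < best) { best = mm; bests.clear(); }
        if (mm == best) bests.push_back({start, strand == 0 ? 1 : -1});
      }
    }
    if (!bests.empty()) {
      best_mm[r] = best;
      n_best[r] = (int)bests.size();
      record(tie_read, tie_pos, tie_strand, r + 1, bests);
    }
  }
  return List::create(_["best_mm"] = best_mm, _["n_best"] = n_best,
                      _["too_long"] = too_long, _["tie_read"] = wrap(tie_read),
                      _["tie_pos"] = wrap(tie_pos),
                      _["tie_strand"] = wrap(tie_strand));
}

// Per-position base counts and quality sums from reference-oriented reads.
// Non-ACGT read bases contribute nothing (they are excluded from depth).
// [[Rcpp::export]]
List cpp_pileup(CharacterVector seqs, CharacterVector quals,
                IntegerVector starts, int ref_len, int qual_offset) {
  IntegerMatrix counts(4, ref_len);
  NumericMatrix qsum(4, ref_len);
  const int n = seqs.size();
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    if (s.size() != q.size()) stop("base/quality length mismatch in pileup");
    const int st = starts[i];
    for (int j = 0; j < (int)s.size(); ++j) {
      int e = enc(s[j]);
      if (e < 0) continue;
      int pos = st + j;
      if (pos < 0 || pos >= ref_len) continue;
      counts(e, pos) += 1;
      qsum(e, pos) += (double)(q[j] - qual_offset);
    }
  }
  return List::create(_["counts"] = counts, _["qualsum"] = qsum);
}
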