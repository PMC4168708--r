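#include "xmb_util.h"

using namespace Rcpp;

// [[Rcpp::export]]
int cpp_hamming(std::string x, std::string y) {
  if (x.size() != y.size()) stop("hamming: sequences must have equal length");
  return hamming_raw(x.c_str(), y.c_str(), (int)x.size());
}

// [[Rcpp::export]]
bool cpp_ra_match(std::string x, std::string y, int liid, double alpha) {
  if (x.size() != y.size()) stop("ra_match: segments must have equal length");
  int W = (int)x.size();
  if (W < liid) stop("ra_match: segment length below l_iid");
  return ra_match_raw(x.c_str(), y.c_str(), W, liid, alpha);
}

// Maximum W in [liid, min(|r1|,|r2|)] with suffix_W(r1) RA-matching
// prefix_W(r2); 0 if none. Scans W descending, first hit is the maximum.
// [[Rcpp::export]]
int cpp_ra_overlap(std::string r1, std::string r2, int liid, double alpha) {
  int n1 = (int)r1.size(), n2 = (int)r2.size();
  int wmax = std::min(n1, n2);
  for (int W = wmax; W >= liid; --W) {
    if (ra_match_raw(r1.c_str() + n1 - W, r2.c_str(), W, liid, alpha))
      return W;
  }
  return 0;
}

// All read pairs sharing at least one exact f-mer, with the implied offsets.
// offset o means read j starts o bases after read i (in read-i coordinates);
// o may be negative. At most max_offsets distinct offsets per ordered pair
// are retained (most-voted first-seen). index_stride subsamples the indexed
// positions of each read; shared f-mer runs longer than the stride are still
// detected.
// [[Rcpp::export]]
DataFrame cpp_fingerprint_candidates(CharacterVector reads, int f,
                                     int max_offsets = 5,
                                     int index_stride = 1) {
  int N = reads.size();
  std::vector<std::string> rd(N);
  for (int k = 0; k < N; ++k) rd[k] = as<std::string>(reads[k]);

  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  for (int k = 0; k < N; ++k) {
    int n = (int)rd[k].size();
    for (int q = 0; q + f <= n; q += index_stride) {
      uint64_t key;
      if (pack_kmer(rd[k].c_str() + q, f, key)) index[key].push_back({k, q});
    }
  }
  // votes per (i, j, offset); key packs i, j into one 64-bit value
  std::unordered_map<uint64_t, std::unordered_map<int, int>> votes;
  for (int k = 0; k < N; ++k) {
    int n = (int)rd[k].size();
    for (int q = 0; q + f <= n; ++q) {
      uint64_t key;
      if (!pack_kmer(rd[k].c_str() + q, f, key)) continue;
      auto it = index.find(key);
      if (it == index.end()) continue;
      for (auto &hit : it->second) {
        int j = hit.first, qj = hit.second;
        if (j <= k) continue;  // unordered pairs, i < j
        int off = q - qj;      // j starts off after i
        uint64_t pkey = ((uint64_t)k << 32) | (uint32_t)j;
        votes[pkey][off]++;
      }
    }
  }
  std::vector<int> iv, jv, ov, vv;
  for (auto &pe : votes) {
    int i = (int)(pe.first >> 32), j = (int)(pe.first & 0xffffffffu);
    // order offsets by vote count descending, keep max_offsets
    std::vector<std::pair<int, int>> offs(pe.second.begin(), pe.second.end());
    std::sort(offs.begin(), offs.end(), [](const std::pair<int, int> &a,
                                           const std::pair<int, int> &b) {
      if (a.second != b.second) return a.second > b.second;
      return a.first < b.first;
    });
    int keep = std::min((int)offs.size(), max_offsets);
    for (int k = 0; k < keep; ++k) {
      iv.push_back(i + 1);
      jv.push_back(j + 1);
      ov.push_back(offs[k].first);
      vv.push_back(offs[k].second);
    }
  }
  return DataFrame::create(_["i"] = iv, _["j"] = jv, _["offset"] = ov,
                           _["votes"] = vv);
}

// Verify substitution-mode candidates at their fingerprint-implied offsets.
// Candidates are canonicalised so offset >= 0 (swap roles if negative):
// returned rows (i, j, offset, W) mean suffix_W(read i) RA-matches
// prefix_W(read j) at W = implied overlap.
// [[Rcpp::export]]
DataFrame cpp_verify_sub(CharacterVector reads, IntegerVector ci,
                         IntegerVector cj, IntegerVector coffset, int liid,
                         double alpha) {
  int N = reads.size();
  std::vector<std::string> rd(N);
  for (int k = 0; k < N; ++k) rd[k] = as<std::string>(reads[k]);
  std::vector<int> iv, jv, ov, wv;
  int M = ci.size();
  for (int m = 0; m < M; ++m) {
    int a = ci[m] - 1, b = cj[m] - 1, o = coffset[m];
    if (o < 0) { std::swap(a, b); o = -o; }
    int na = (int)rd[a].size(), nb = (int)rd[b].size();
    int W = std::min(na - o, nb);
    if (W < liid) continue;
    if (ra_match_raw(rd[a].c_str() + o, rd[b].c_str(), W, liid, alpha)) {
      iv.push_back(a + 1);
      jv.push_back(b + 1);
      ov.push_back(o);
      wv.push_back(W);
    }
  }
  return DataFrame::create(_["i"] = iv, _["j"] = jv, _["offset"] = ov,
                           _["W"] = wv);
}

// Greedy contig chaining: candidates must be pre-sorted by (W desc, i, j).
// Accepts a successor link i -> j when i has no successor, j no predecessor,
// and the link does not close a cycle. Returns successor pointers (0 = none).
// [[Rcpp::export]]
List cpp_greedy_chain(int n, IntegerVector ci, IntegerVector cj) {
  std::vector<int> succ(n + 1, 0), pred(n + 1, 0);
  UnionFind uf(n + 1);
  int M = ci.size();
  for (int m = 0; m < M; ++m) {
    int a = ci[m], b = cj[m];
    if (a == b) continue;
    if (succ[a] != 0 || pred[b] != 0) continue;
    if (uf.find(a) == uf.find(b)) continue;  // would close a cycle
    succ[a] = b;
    pred[b] = a;
    uf.unite(a, b);
  }
  IntegerVector s(n), p(n);
  for (int k = 1; k <= n; ++k) { s[k - 1] = succ[k]; p[k - 1] = pred[k]; }
  return List::create(_["succ"] = s, _["pred"] = p);
}
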