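#include "xmb_util.h"
#include <algorithm>

using namespace Rcpp;

// Suffix array by direct suffix sort. Adequate for the genome sizes this
// package simulates (up to a few hundred kb): comparisons terminate at the
// first mismatch, which for random background is O(log n) expected.
static void suffix_array(const std::string &s, std::vector<int> &sa) {
  int n = (int)s.size();
  sa.resize(n);
  for (int k = 0; k < n; ++k) sa[k] = k;
  const char *p = s.c_str();
  std::sort(sa.begin(), sa.end(), [&](int a, int b) {
    int la = n - a, lb = n - b, m = std::min(la, lb);
    int c = memcmp(p + a, p + b, (size_t)m);
    if (c != 0) return c < 0;
    return la < lb;
  });
}

// Kasai LCP: lcp[i] = longest common prefix of suffixes sa[i-1], sa[i].
static void lcp_array(const std::string &s, const std::vector<int> &sa,
                      std::vector<int> &lcp) {
  int n = (int)s.size();
  std::vector<int> rank(n);
  for (int k = 0; k < n; ++k) rank[sa[k]] = k;
  lcp.assign(n, 0);
  int h = 0;
  for (int k = 0; k < n; ++k) {
    if (rank[k] > 0) {
      int j = sa[rank[k] - 1];
      while (k + h < n && j + h < n && s[k + h] == s[j + h]) ++h;
      lcp[rank[k]] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }
}

// Longest substring occurring at >= 2 (resp. 3) distinct origins. For
// circular genomes the caller passes the doubled string and mod_g = G;
// positions equal mod G are the same origin and lengths cap at G. mod_g = 0
// means linear (every position its own origin). The required occurrences sit
// close together in suffix-array order: scanning back over a bounded window
// while taking the running LCP minimum and collecting distinct origins finds
// the maximum (duplicated suffixes of the doubled string contribute at most
// one extra entry each).
// [[Rcpp::export]]
List cpp_longest_exact(std::string s, int mod_g = 0) {
  int n = (int)s.size();
  if (n < 2) return List::create(_["len"] = 0, _["t1"] = -1, _["t2"] = -1);
  std::vector<int> sa, lcp;
  suffix_array(s, sa);
  lcp_array(s, sa, lcp);
  auto origin = [&](int p) { return mod_g > 0 ? p % mod_g : p; };
  int best = 0, b1 = -1, b2 = -1;
  const int LOOKBACK = 8;
  for (int k = 1; k < n; ++k) {
    int run = lcp[k];
    for (int j = k - 1; j >= 0 && j >= k - LOOKBACK; --j) {
      if (run <= best) break;
      if (origin(sa[j]) != origin(sa[k])) {
        int len = run;
        if (mod_g > 0 && len > mod_g) len = mod_g;
        if (len > best) { best = len; b1 = sa[j]; b2 = sa[k]; }
        break;
      }
      if (j > 0) run = std::min(run, lcp[j]);
    }
  }
  if (b1 > b2) std::swap(b1, b2);
  if (mod_g > 0 && b1 >= 0) { b1 = origin(b1); b2 = origin(b2); }
  return List::create(_["len"] = best, _["t1"] = b1, _["t2"] = b2);
}

// [[Rcpp::export]]
List cpp_longest_triple(std::string s, int mod_g = 0) {
  int n = (int)s.size();
  if (n < 3) return List::create(_["len"] = 0, _["t"] = IntegerVector::create());
  std::vector<int> sa, lcp;
  suffix_array(s, sa);
  lcp_array(s, sa, lcp);
  auto origin = [&](int p) { return mod_g > 0 ? p % mod_g : p; };
  int best = 0;
  std::vector<int> bt;
  const int LOOKBACK = 16;
  for (int k = 2; k < n; ++k) {
    int run = lcp[k];
    std::vector<int> orig = {origin(sa[k])};
    std::vector<int> pos = {sa[k]};
    for (int j = k - 1; j >= 0 && j >= k - LOOKBACK; --j) {
      if (run <= best) break;
      int o = origin(sa[j]);
      bool dup = false;
      for (int q : orig) if (q == o) { dup = true; break; }
      if (!dup) {
        orig.push_back(o);
        pos.push_back(sa[j]);
        if ((int)orig.size() == 3) {
          int len = run;
          if (mod_g > 0 && len > mod_g) len = mod_g;
          if (len > best) { best = len; bt = pos; }
          break;
        }
      }
      if (j > 0) run = std::min(run, lcp[j]);
    }
  }
  if (best == 0)
    return List::create(_["len"] = 0, _["t"] = IntegerVector::create());
  IntegerVector t(3);
  for (int k = 0; k < 3; ++k) t[k] = mod_g > 0 ? bt[k] % mod_g : bt[k];
  std::sort(t.begin(), t.end());
  return List::create(_["len"] = best, _["t"] = t);
}

// Enumerate left-maximal repeated position pairs with common extension at
// least floor_len. Pairs are grouped from runs of consecutive suffixes whose
// adjacent LCPs all reach floor_len; within a run every suffix pair shares a
// floor_len prefix. Right-maximality is automatic (len = full common
// extension); left-maximality is filtered explicitly.
// [[Rcpp::export]]
DataFrame cpp_repeat_pairs(std::string s, int floor_len) {
  int n = (int)s.size();
  std::vector<int> t1v, t2v, lenv;
  if (n >= 2 && floor_len >= 1) {
    std::vector<int> sa, lcp;
    suffix_array(s, sa);
    lcp_array(s, sa, lcp);
    int run_start = 0;
    for (int k = 1; k <= n; ++k) {
      bool extend = (k < n) && (lcp[k] >= floor_len);
      if (!extend) {
        int run_end = k - 1;  // run covers sa[run_start .. run_end]
        int m = run_end - run_start + 1;
        if (m >= 2) {
          for (int a = run_start; a < run_end; ++a) {
            for (int b = a + 1; b <= run_end; ++b) {
              int pa = sa[a], pb = sa[b];
              if (pa > pb) std::swap(pa, pb);
              // left-maximal?
              if (pa > 0 && pb > 0 && s[pa - 1] == s[pb - 1]) continue;
              // full common extension
              int len = 0;
              while (pb + len < n && s[pa + len] == s[pb + len]) ++len;
              if (len >= floor_len) {
                t1v.push_back(pa);
                t2v.push_back(pb);
                lenv.push_back(len);
              }
            }
          }
        }
        run_start = k;
      }
    }
  }
  return DataFrame::create(_["t1"] = t1v, _["t2"] = t2v, _["len"] = lenv);
}
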