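#ifndef XMB_UTIL_H
#define XMB_UTIL_H

#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
#include <cstdint>

// Disjoint-set forest with path halving + union by size.
struct UnionFind {
  std::vector<int> parent;
  std::vector<int> sz;
  explicit UnionFind(int n) : parent(n), sz(n, 1) {
    for (int k = 0; k < n; ++k) parent[k] = k;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (sz[a] < sz[b]) std::swap(a, b);
    parent[b] = a;
    sz[a] += sz[b];
  }
};

// 2-bit packing of ACGT; returns false if a non-ACGT byte is hit.
inline bool pack_kmer(const char *s, int f, uint64_t &out) {
  uint64_t v = 0;
  for (int k = 0; k < f; ++k) {
    uint64_t code;
    switch (s[k]) {
      case 'A': code = 0; break;
      case 'C': code = 1; break;
      case 'G': code = 2; break;
      case 'T': code = 3; break;
      default: return false;
    }
    v = (v << 2) | code;
  }
  out = v;
  return true;
}

inline int hamming_raw(const char *x, const char *y, int n) {
  int d = 0;
  for (int k = 0; k < n; ++k) d += (x[k] != y[k]);
  return d;
}

// RA-matching: whole-segment and both length-liid end anchors must each have
// mismatch count strictly below alpha * (their length).
inline bool ra_match_raw(const char *x, const char *y, int W, int liid,
                         double alpha) {
  if (W < liid) return false;
  int dpre = hamming_raw(x, y, liid);
  if (!(dpre < alpha * liid)) return false;
  int dsuf = hamming_raw(x + W - liid, y + W - liid, liid);
  if (!(dsuf < alpha * liid)) return false;
  int d = dpre;
  if (W > liid) {
    // middle section plus suffix anchor already counted pieces carefully:
    // recount the middle [liid, W-liid) then add both anchors, avoiding
    // double counting when the anchors overlap (W < 2*liid).
    if (W >= 2 * liid) {
      d = dpre + dsuf + hamming_raw(x + liid, y + liid, W - 2 * liid);
    } else {
      d = hamming_raw(x, y, W);
    }
  }
  return d < alpha * W;
}

#endif
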