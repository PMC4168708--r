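#include "xmb_util.h"
#include <algorithm>

using namespace Rcpp;

int overlap_align_map(const char *x, int nx, const char *y, int ny, int band,
                      std::vector<int> &map_xy, std::vector<uint8_t> &edit_x);

struct SlotLayout {
  std::vector<int> start;  // slot id base per read (0-based, exclusive scan)
  std::vector<int> nslot;
  int total = 0;
  SlotLayout(const std::vector<std::string> &rd, int K) {
    int N = (int)rd.size();
    start.resize(N);
    nslot.resize(N);
    for (int k = 0; k < N; ++k) {
      start[k] = total;
      nslot[k] = std::max(0, (int)rd[k].size() - K + 1);
      total += nslot[k];
    }
  }
};


static std::vector<int> labels_from_uf(const SlotLayout &lay, UnionFind &uf) {
  int total = lay.total;
  std::vector<int> label(total, 0), out(total, 0);
  int C = 0;
  for (int s = 0; s < total; ++s) {
    int r = uf.find(s);
    if (label[r] == 0) label[r] = ++C;
    out[s] = label[r];
  }
  return out;
}

// slot_label: 1-based preliminary cluster label per slot
static List finish_clusters(const std::vector<std::string> &rd, int K,
                            const SlotLayout &lay,
                            const std::vector<int> &slot_label,
                            int min_support = 1) {
  int N = (int)rd.size();
  int total = lay.total;
  int C0 = 0;
  for (int s = 0; s < total; ++s) C0 = std::max(C0, slot_label[s]);
  std::vector<int> size0(C0, 0);
  std::vector<int> rep_slot0(C0, -1);
  for (int s = 0; s < total; ++s) {
    int c = slot_label[s] - 1;
    size0[c]++;
    if (rep_slot0[c] < 0) rep_slot0[c] = s;
  }
  // drop clusters below the support threshold (isolated near-indel slots);
  // their loci remain represented by the main clusters
  std::vector<int> remap(C0, 0);
  int C = 0;
  std::vector<int> rep_slot;
  for (int c = 0; c < C0; ++c) {
    if (size0[c] >= min_support) {
      remap[c] = ++C;
      rep_slot.push_back(rep_slot0[c]);
    }
  }
  IntegerVector assign(total), slot_read(total), slot_pos(total);
  std::vector<int> sizes(C, 0);
  for (int k = 0; k < N; ++k) {
    for (int q = 0; q < lay.nslot[k]; ++q) {
      int s = lay.start[k] + q;
      int c = remap[slot_label[s] - 1];
      assign[s] = c;
      slot_read[s] = k + 1;
      slot_pos[s] = q;
      if (c > 0) sizes[c - 1]++;
    }
  }
  CharacterVector reps(C);
  for (int c = 0; c < C; ++c) {
    int s = rep_slot[c];
    // locate owning read by binary search on layout
    int lo = 0, hi = N - 1;
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (lay.start[mid] <= s) lo = mid; else hi = mid - 1;
    }
    int q = s - lay.start[lo];
    reps[c] = rd[lo].substr(q, K);
  }
  // per-cluster consensus of the final K-mer base (majority over members);
  // spelled contigs append this base per cluster, which denoises the output
  // at any reasonable depth
  std::vector<std::array<int, 4>> lastc(C, {0, 0, 0, 0});
  for (int k = 0; k < N; ++k) {
    for (int q = 0; q < lay.nslot[k]; ++q) {
      int c = assign[lay.start[k] + q] - 1;
      if (c < 0) continue;
      char b = rd[k][q + K - 1];
      int code = (b == 'A') ? 0 : (b == 'C') ? 1 : (b == 'G') ? 2 :
                 (b == 'T') ? 3 : -1;
      if (code >= 0) lastc[c][code]++;
    }
  }
  CharacterVector cons_last(C);
  const char *alpha_ = "ACGT";
  for (int c = 0; c < C; ++c) {
    int best = 0;
    for (int b = 1; b < 4; ++b) if (lastc[c][b] > lastc[c][best]) best = b;
    cons_last[c] = std::string(1, alpha_[best]);
  }
  // edges from consecutive slots within reads
  std::unordered_map<uint64_t, int> ecount;
  int self_edges = 0;
  for (int k = 0; k < N; ++k) {
    for (int q = 0; q + 1 < lay.nslot[k]; ++q) {
      int u = assign[lay.start[k] + q], v = assign[lay.start[k] + q + 1];
      if (u == 0 || v == 0) continue;
      if (u == v) { ++self_edges; continue; }
      ecount[((uint64_t)u << 32) | (uint32_t)v]++;
    }
  }
  std::vector<int> eu, ev, en;
  eu.reserve(ecount.size());
  for (auto &e : ecount) {
    eu.push_back((int)(e.first >> 32));
    ev.push_back((int)(e.first & 0xffffffffu));
    en.push_back(e.second);
  }
  return List::create(
      _["assign"] = assign, _["slot_read"] = slot_read,
      _["slot_pos"] = slot_pos, _["reps"] = reps,
      _["cons_last"] = cons_last,
      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()),
      _["edges"] = DataFrame::create(_["u"] = eu, _["v"] = ev, _["n"] = en),
      _["self_edges"] = self_edges);
}

// Substitution-mode K-mer clustering: union K-mer slots at aligned offsets of
// verified RA-overlapping read pairs (offset >= 0: read j starts offset bases
// after read i).
// [[Rcpp::export]]
List cpp_cluster_sub(CharacterVector reads, IntegerVector pi, IntegerVector pj,
                     IntegerVector poffset, int K) {
  int N = reads.size();
  std::vector<std::string> rd(N);
  for (int k = 0; k < N; ++k) rd[k] = as<std::string>(reads[k]);
  SlotLayout lay(rd, K);
  UnionFind uf(lay.total);
  int M = pi.size();
  for (int m = 0; m < M; ++m) {
    int a = pi[m] - 1, b = pj[m] - 1, o = poffset[m];
    if (o < 0) { std::swap(a, b); o = -o; }
    int tlo = o, thi = std::min((int)rd[a].size() - K,
                                o + (int)rd[b].size() - K);
    for (int t = std::max(tlo, 0); t <= thi; ++t) {
      uf.unite(lay.start[a] + t, lay.start[b] + (t - o));
    }
  }
  std::vector<int> label = labels_from_uf(lay, uf);
  return finish_clusters(rd, K, lay, label);
}

// Indel-mode clustering: banded overlap alignment of each candidate pair;
// accepted alignments (RA-style edit-density test on the whole overlap and on
// both l_iid end windows) union the K-mer slots whose start positions are
// matched by the alignment path.
// [[Rcpp::export]]
List cpp_cluster_indel(CharacterVector reads, IntegerVector pi,
                       IntegerVector pj, IntegerVector poffset, int K,
                       int band, double alpha, int liid, int min_run = 5,
                       int min_support = 1) {
  int N = reads.size();
  std::vector<std::string> rd(N);
  for (int k = 0; k < N; ++k) rd[k] = as<std::string>(reads[k]);
  SlotLayout lay(rd, K);
  UnionFind uf(lay.total);
  int M = pi.size();
  int accepted = 0;
  std::unordered_map<uint64_t, bool> seen;  // first accepted offset per pair
  std::vector<int> map_xy;
  std::vector<uint8_t> edit_x;
  for (int m = 0; m < M; ++m) {
    int a = pi[m] - 1, b = pj[m] - 1, o = poffset[m];
    if (o < 0) { std::swap(a, b); o = -o; }
    uint64_t pkey = ((uint64_t)a << 32) | (uint32_t)b;
    auto sit = seen.find(pkey);
    if (sit != seen.end() && sit->second) continue;
    int na = (int)rd[a].size(), nb = (int)rd[b].size();
    int W0 = std::min(na - o, nb);
    if (W0 < liid) continue;
    if (W0 < K) continue;  // overlap holds no complete K-window to union
    const char *x = rd[a].c_str() + o;
    int nx = na - o;
    int dist = overlap_align_map(x, nx, rd[b].c_str(), nb, band, map_xy,
                                 edit_x);
    if (dist < 0) continue;
    nx = (int)map_xy.size();
    if (!(dist < alpha * W0)) { seen[pkey] = false; continue; }
    int epre = 0, esuf = 0;
    int npre = std::min(liid, nx);
    for (int t = 0; t < npre; ++t) epre += edit_x[t];
    for (int t = std::max(0, nx - liid); t < nx; ++t) esuf += edit_x[t];
    if (!(epre < alpha * liid) || !(esuf < alpha * liid)) {
      seen[pkey] = false;
      continue;
    }
    seen[pkey] = true;
    ++accepted;
    // union only at positions inside clean diagonal runs of the alignment
    // (>= MIN_RUN consecutive matched columns); near indels the optimal
    // path is ambiguous and would occasionally union adjacent loci,
    // merging neighbouring clusters into tangles
    const int MIN_RUN = min_run;
    int run = 0, map_prev = -2;
    for (int t = 0; t <= nx; ++t) {
      bool matched = t < nx && map_xy[t] >= 0 && edit_x[t] == 0;
      bool contiguous = matched && run > 0 && map_xy[t] == map_prev + 1;
      if (matched && (run == 0 || contiguous)) {
        ++run;
        map_prev = map_xy[t];
        continue;
      }
      if (run >= MIN_RUN) {
        for (int s2 = t - run; s2 < t; ++s2) {
          int u = o + s2, v = map_xy[s2];
          if (u <= na - K && v <= nb - K) {
            uf.unite(lay.start[a] + u, lay.start[b] + v);
          }
        }
      }
      if (matched) { run = 1; map_prev = map_xy[t]; } else run = 0;
    }
  }
  std::vector<int> label = labels_from_uf(lay, uf);
  List out = finish_clusters(rd, K, lay, label, min_support);
  out["accepted_pairs"] = accepted;
  return out;
}

// Pairwise banded overlap alignment statistics (indel mode surface): for each
// candidate pair, the edit distance, overlap length and acceptance flag.
// [[Rcpp::export]]
DataFrame cpp_overlap_align_stats(CharacterVector reads, IntegerVector pi,
                                  IntegerVector pj, IntegerVector poffset,
                                  int band, double alpha, int liid) {
  int N = reads.size();
  std::vector<std::string> rd(N);
  for (int k = 0; k < N; ++k) rd[k] = as<std::string>(reads[k]);
  int M = pi.size();
  std::vector<int> iv, jv, ov, dv, wv;
  std::vector<bool> ac;
  std::vector<int> map_xy;
  std::vector<uint8_t> edit_x;
  for (int m = 0; m < M; ++m) {
    int a = pi[m] - 1, b = pj[m] - 1, o = poffset[m];
    if (o < 0) { std::swap(a, b); o = -o; }
    int na = (int)rd[a].size(), nb = (int)rd[b].size();
    int W0 = std::min(na - o, nb);
    if (W0 < 1) continue;
    int dist = overlap_align_map(rd[a].c_str() + o, na - o, rd[b].c_str(), nb,
                                 band, map_xy, edit_x);
    if (dist < 0) continue;
    int nx = (int)map_xy.size();
    int epre = 0, esuf = 0;
    for (int t = 0; t < std::min(liid, nx); ++t) epre += edit_x[t];
    for (int t = std::max(0, nx - liid); t < nx; ++t) esuf += edit_x[t];
    bool ok = (W0 >= liid) && (dist < alpha * W0) && (epre < alpha * liid) &&
              (esuf < alpha * liid);
    iv.push_back(a + 1); jv.push_back(b + 1); ov.push_back(o);
    dv.push_back(dist); wv.push_back(W0); ac.push_back(ok);
  }
  return DataFrame::create(_["i"] = iv, _["j"] = jv, _["offset"] = ov,
                           _["dist"] = dv, _["W"] = wv,
                           _["accepted"] = LogicalVector(ac.begin(), ac.end()));
}

// Component joining partner search (Alg 2 step 4): every node lacking a
// successor (tail) or predecessor (head) is linked to its best RA-overlap-W
// partner among ALL cluster representatives, W descending from K-1 to
// l_iid. The partner may already have neighbours (a repeat-boundary cluster
// legitimately has two), but no node gains more than one new link per
// direction in this step. Ties: larger cluster, then lower ids.
// [[Rcpp::export]]
DataFrame cpp_join_search(CharacterVector reps, IntegerVector sizes,
                          IntegerVector need_succ, IntegerVector need_pred,
                          int liid, double alpha, int f, int wmin,
                          int index_stride = 2) {
  int C = reps.size();
  std::vector<std::string> rp(C);
  for (int k = 0; k < C; ++k) rp[k] = as<std::string>(reps[k]);
  int K = C > 0 ? (int)rp[0].size() : 0;

  // f-mer index over ALL representatives (strided)
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  for (int v = 1; v <= C; ++v) {
    const std::string &s = rp[v - 1];
    for (int q = 0; q + f <= (int)s.size(); q += index_stride) {
      uint64_t key;
      if (pack_kmer(s.c_str() + q, f, key)) index[key].push_back({v, q});
    }
  }
  struct Cand { int u, v, W, size; };
  std::vector<Cand> cands;
  std::unordered_map<uint64_t, bool> seen;
  auto consider = [&](int u, int v, int o) {
    if (u == v || o < 1) return;
    int W = K - o;
    if (W < std::max(liid, wmin)) return;
    uint64_t ck = (((uint64_t)u << 40) ^ ((uint64_t)v << 20)) | (uint32_t)o;
    if (seen.count(ck)) return;
    seen[ck] = true;
    if (ra_match_raw(rp[u - 1].c_str() + o, rp[v - 1].c_str(), W, liid,
                     alpha)) {
      cands.push_back({u, v, W, sizes[v - 1] + sizes[u - 1]});
    }
  };
  // tails query as the left partner (u at q, hit at qv, offset o = q - qv)
  for (int k = 0; k < need_succ.size(); ++k) {
    int u = need_succ[k];
    const std::string &s = rp[u - 1];
    for (int q = 0; q + f <= (int)s.size(); ++q) {
      uint64_t key;
      if (!pack_kmer(s.c_str() + q, f, key)) continue;
      auto it = index.find(key);
      if (it == index.end()) continue;
      for (auto &hit : it->second) consider(u, hit.first, q - hit.second);
    }
  }
  // heads query as the right partner
  for (int k = 0; k < need_pred.size(); ++k) {
    int v = need_pred[k];
    const std::string &s = rp[v - 1];
    for (int qv = 0; qv + f <= (int)s.size(); ++qv) {
      uint64_t key;
      if (!pack_kmer(s.c_str() + qv, f, key)) continue;
      auto it = index.find(key);
      if (it == index.end()) continue;
      for (auto &hit : it->second) consider(hit.first, v, hit.second - qv);
    }
  }
  std::sort(cands.begin(), cands.end(), [](const Cand &a, const Cand &b) {
    if (a.W != b.W) return a.W > b.W;
    if (a.size != b.size) return a.size > b.size;
    if (a.u != b.u) return a.u < b.u;
    return a.v < b.v;
  });
  std::vector<bool> succ_new(C + 1, false), pred_new(C + 1, false);
  std::vector<bool> succ_open(C + 1, false), pred_open(C + 1, false);
  for (int k = 0; k < need_succ.size(); ++k) succ_open[need_succ[k]] = true;
  for (int k = 0; k < need_pred.size(); ++k) pred_open[need_pred[k]] = true;
  std::vector<int> ju, jv, jw;
  for (auto &c : cands) {
    if (succ_new[c.u] || pred_new[c.v]) continue;
    if (!succ_open[c.u] && !pred_open[c.v]) continue;
    succ_new[c.u] = true;
    pred_new[c.v] = true;
    ju.push_back(c.u);
    jv.push_back(c.v);
    jw.push_back(c.W);
  }
  return DataFrame::create(_["u"] = ju, _["v"] = jv, _["W"] = jw);
}
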