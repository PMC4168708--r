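#include "xmb_util.h"

using namespace Rcpp;

// Banded global edit distance (unit costs). Cells with |i - j| > band are
// outside the band. Returns -1 if the true distance may exceed the band
// (caller should widen and retry).
// [[Rcpp::export]]
int cpp_banded_edit(std::string a, std::string b, int band) {
  int n = (int)a.size(), m = (int)b.size();
  if (std::abs(n - m) > band) return -1;
  const int INF = 1 << 29;
  int width = 2 * band + 1;
  std::vector<int> prev(width, INF), cur(width, INF);
  // column index j stored at j - (i - band)
  for (int j = 0; j <= std::min(m, band); ++j) prev[j + band] = j;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    int jlo = std::max(0, i - band), jhi = std::min(m, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      // row window shifts right by one per row: cell (i-1, j-1) sits at the
      // same band index as (i, j); (i-1, j) sits one to the right
      int idx = j - (i - band);
      int best = INF;
      if (j == 0) best = i;
      if (j > 0 && prev[idx] < INF) {
        int v = prev[idx] + (a[i - 1] == b[j - 1] ? 0 : 1);
        if (v < best) best = v;
      }
      if (idx + 1 < width && prev[idx + 1] < INF) {  // deletion in b (down)
        int v = prev[idx + 1] + 1;
        if (v < best) best = v;
      }
      if (idx - 1 >= 0 && cur[idx - 1] < INF) {  // insertion (left)
        int v = cur[idx - 1] + 1;
        if (v < best) best = v;
      }
      cur[idx] = best;
    }
    std::swap(prev, cur);
  }
  int res = prev[m - (n - band)];
  if (res >= INF) return -1;
  if (res > band) return -1;  // band may have clipped a better path
  return res;
}

// Banded overlap alignment of x against y with traceback. Global in both up
// to the point where either sequence is consumed (free terminal gap on the
// other). Fills map_xy (for every x position aligned to a y position on a
// match/substitution column, the y position; -1 otherwise) and the mismatch
// pattern along x. Returns total edit distance of the best path, or -1.
int overlap_align_map(const char *x, int nx, const char *y, int ny, int band,
                      std::vector<int> &map_xy, std::vector<uint8_t> &edit_x) {
  const int INF = 1 << 29;
  int width = 2 * band + 1;
  if (std::abs(nx - ny) > band) {
    // free end absorbs the difference; band only needs to cover drift within
    // the aligned region, so clamp the longer one.
    if (nx > ny + band) nx = ny + band;
    if (ny > nx + band) ny = nx + band;
  }
  std::vector<int> dp((size_t)(nx + 1) * width, INF);
  std::vector<uint8_t> dir((size_t)(nx + 1) * width, 0);  // 1 diag 2 up 3 left
  auto at = [&](int i, int j) -> int & {
    return dp[(size_t)i * width + (j - (i - band))];
  };
  auto dirat = [&](int i, int j) -> uint8_t & {
    return dir[(size_t)i * width + (j - (i - band))];
  };
  for (int j = 0; j <= std::min(ny, band); ++j) { at(0, j) = j; dirat(0, j) = 3; }
  for (int i = 1; i <= nx; ++i) {
    int jlo = std::max(0, i - band), jhi = std::min(ny, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      int best = INF; uint8_t d = 0;
      if (j == 0) { best = i; d = 2; }
      if (j > 0 && j - 1 >= (i - 1) - band && j - 1 <= (i - 1) + band) {
        int v = at(i - 1, j - 1) + (x[i - 1] == y[j - 1] ? 0 : 1);
        if (v < best) { best = v; d = 1; }
      }
      if (j >= (i - 1) - band && j <= (i - 1) + band) {
        int v = at(i - 1, j) + 1;
        if (v < best) { best = v; d = 2; }
      }
      if (j - 1 >= i - band) {
        int v = at(i, j - 1) + 1;
        if (v < best) { best = v; d = 3; }
      }
      at(i, j) = best; dirat(i, j) = d;
    }
  }
  // terminal: consume all of x (free end of y) or all of y (free end of x)
  int best = INF, bi = -1, bj = -1;
  for (int j = std::max(0, nx - band); j <= std::min(ny, nx + band); ++j) {
    if (at(nx, j) < best) { best = at(nx, j); bi = nx; bj = j; }
  }
  for (int i = std::max(0, ny - band); i <= std::min(nx, ny + band); ++i) {
    if (ny >= i - band && ny <= i + band && at(i, ny) < best) {
      best = at(i, ny); bi = i; bj = ny;
    }
  }
  if (best >= INF) return -1;
  map_xy.assign(nx, -1);
  edit_x.assign(nx, 0);
  int i = bi, j = bj;
  while (i > 0 || j > 0) {
    if (j < i - band || j > i + band) break;
    uint8_t d = dirat(i, j);
    if (d == 1) {
      map_xy[i - 1] = j - 1;
      edit_x[i - 1] = (x[i - 1] == y[j - 1]) ? 0 : 1;
      --i; --j;
    } else if (d == 2) {
      edit_x[i - 1] = 1;  // deletion of x base relative to y
      --i;
    } else if (d == 3) {
      --j;
    } else {
      break;
    }
  }
  return best;
}
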