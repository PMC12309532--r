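#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// 3x3 square binary erosion; pixels outside the image are background.
// [[Rcpp::export]]
LogicalMatrix cpp_erode(const LogicalMatrix& mask, int iterations) {
  int H = mask.nrow(), W = mask.ncol();
  std::vector<char> cur(H * (size_t)W), nxt(H * (size_t)W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      cur[(size_t)c * H + r] = mask(r, c) ? 1 : 0;
  for (int it = 0; it < iterations; ++it) {
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        char keep = 1;
        if (r == 0 || r == H - 1 || c == 0 || c == W - 1) {
          keep = 0;  // border pixels always have an out-of-bounds neighbour
        } else {
          for (int dc = -1; dc <= 1 && keep; ++dc)
            for (int dr = -1; dr <= 1 && keep; ++dr)
              if (!cur[(size_t)(c + dc) * H + (r + dr)]) keep = 0;
        }
        nxt[(size_t)c * H + r] = keep && cur[(size_t)c * H + r];
      }
    }
    std::swap(cur, nxt);
  }
  LogicalMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      out(r, c) = cur[(size_t)c * H + r] != 0;
  return out;
}

// Despeckling by circular-median comparison: replace a pixel by the median
// of its disk neighbourhood (offsets with Euclidean distance <= radius,
// centre included) when it deviates from that median by more than
// `threshold` in the stated direction. Lower-median convention for
// even-sized clamped border neighbourhoods.
// [[Rcpp::export]]
IntegerMatrix cpp_remove_outliers(const IntegerMatrix& img, double radius,
                                  double threshold, bool bright) {
  int H = img.nrow(), W = img.ncol();
  int R = (int)std::floor(radius);
  std::vector<int> offr, offc;
  for (int dr = -R; dr <= R; ++dr)
    for (int dc = -R; dc <= R; ++dc)
      if ((double)dr * dr + (double)dc * dc <= radius * radius) {
        offr.push_back(dr); offc.push_back(dc);
      }
  int K = (int)offr.size();
  IntegerMatrix out(H, W);
  std::vector<int> buf(K);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int n = 0;
      for (int k = 0; k < K; ++k) {
        int rr = r + offr[k], cc = c + offc[k];
        if (rr >= 0 && rr < H && cc >= 0 && cc < W) buf[n++] = img(rr, cc);
      }
      int m = (n - 1) / 2;  // lower median
      std::nth_element(buf.begin(), buf.begin() + m, buf.begin() + n);
      int med = buf[m];
      int v = img(r, c);
      if (bright) {
        out(r, c) = (v - med > threshold) ? med : v;
      } else {
        out(r, c) = (med - v > threshold) ? med : v;
      }
    }
  }
  return out;
}

// Connected-component labeling (4 or 8 connectivity); labels assigned
// 1..K in raster-scan (row-major) order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);  // zero-initialised
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 0, 0, 1};
  static const int dc4[4] = {0, -1, 1, 0};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  int ndir = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int k = 0; k < ndir; ++k) {
          int rr = p.first + dr[k], cc = p.second + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// Moore-neighbour contour tracing of one labeled component starting from
// its first raster pixel; returns counts of axial steps, diagonal steps and
// cyclic direction changes of the 8-direction chain code.
static void trace_chain(const IntegerMatrix& lab, int target, int sr, int sc,
                        int& n_axial, int& n_diag, int& n_corners) {
  int H = lab.nrow(), W = lab.ncol();
  // clockwise Moore neighbourhood starting at W
  static const int dr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  static const int dc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  n_axial = n_diag = n_corners = 0;
  std::vector<int> chain;
  int cr = sr, cc = sc;       // current contour pixel
  int br = sr, bc = sc - 1;   // backtrack (background) cell, W of start
  int p1r = -1, p1c = -1;     // first pixel moved to from the start
  long guard = 0, maxit = 8L * (long)H * W + 16;
  while (true) {
    // direction index from current to backtrack
    int d0 = -1;
    for (int k = 0; k < 8; ++k)
      if (cr + dr[k] == br && cc + dc[k] == bc) { d0 = k; break; }
    int found = -1, fr = 0, fc = 0, pr = br, pc = bc;
    for (int k = 1; k <= 8; ++k) {
      int d = (d0 + k) % 8;
      int rr = cr + dr[d], ccx = cc + dc[d];
      bool fg = rr >= 0 && rr < H && ccx >= 0 && ccx < W && lab(rr, ccx) == target;
      if (fg) { found = d; fr = rr; fc = ccx; break; }
      pr = rr; pc = ccx;  // last background cell scanned
    }
    if (found < 0) break;  // isolated single pixel
    // stop when the initial start->first-successor move would repeat
    if (!chain.empty() && cr == sr && cc == sc && fr == p1r && fc == p1c) break;
    if (chain.empty()) { p1r = fr; p1c = fc; }
    chain.push_back(found);
    br = pr; bc = pc;
    cr = fr; cc = fc;
    if (++guard > maxit) break;  // defensive; cannot occur on valid masks
  }
  int L = (int)chain.size();
  for (int i = 0; i < L; ++i) {
    int d = chain[i];
    if (dr[d] != 0 && dc[d] != 0) ++n_diag; else ++n_axial;
    if (chain[i] != chain[(i + 1) % L]) ++n_corners;
  }
}

// Per-component geometry: pixel count, hole-filled count, bounding box,
// centroid, edge contact and outer-contour chain-code composition.
// [[Rcpp::export]]
DataFrame cpp_measure_components(const IntegerMatrix& lab, int nlab) {
  int H = lab.nrow(), W = lab.ncol();
  IntegerVector npix(nlab), minr(nlab), maxr(nlab), minc(nlab), maxc(nlab);
  IntegerVector firstr(nlab), firstc(nlab);
  NumericVector sumr(nlab), sumc(nlab);
  std::fill(minr.begin(), minr.end(), H);
  std::fill(minc.begin(), minc.end(), W);
  std::fill(maxr.begin(), maxr.end(), -1);
  std::fill(maxc.begin(), maxc.end(), -1);
  std::fill(firstr.begin(), firstr.end(), -1);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int l = lab(r, c);
      if (!l) continue;
      int i = l - 1;
      ++npix[i];
      sumr[i] += r; sumc[i] += c;
      if (r < minr[i]) minr[i] = r;
      if (r > maxr[i]) maxr[i] = r;
      if (c < minc[i]) minc[i] = c;
      if (c > maxc[i]) maxc[i] = c;
      if (firstr[i] < 0) { firstr[i] = r; firstc[i] = c; }
    }
  }
  IntegerVector na(nlab), nd(nlab), nc(nlab), nholes(nlab);
  LogicalVector edge(nlab);
  std::vector<char> vis;
  std::vector<std::pair<int, int> > stack;
  for (int i = 0; i < nlab; ++i) {
    trace_chain(lab, i + 1, firstr[i], firstc[i], na[i], nd[i], nc[i]);
    edge[i] = (minr[i] == 0 || minc[i] == 0 || maxr[i] == H - 1 || maxc[i] == W - 1);
    // hole pixels: non-component cells of the bbox not 4-reachable from its border
    int bh = maxr[i] - minr[i] + 1, bw = maxc[i] - minc[i] + 1;
    vis.assign((size_t)bh * bw, 0);
    stack.clear();
    for (int r = 0; r < bh; ++r)
      for (int c = 0; c < bw; ++c)
        if ((r == 0 || r == bh - 1 || c == 0 || c == bw - 1) && !vis[(size_t)r * bw + c] &&
            lab(minr[i] + r, minc[i] + c) != i + 1) {
          vis[(size_t)r * bw + c] = 1;
          stack.push_back(std::make_pair(r, c));
        }
    static const int dr4[4] = {-1, 0, 0, 1};
    static const int dc4[4] = {0, -1, 1, 0};
    while (!stack.empty()) {
      std::pair<int, int> p = stack.back();
      stack.pop_back();
      for (int k = 0; k < 4; ++k) {
        int rr = p.first + dr4[k], cc = p.second + dc4[k];
        if (rr < 0 || rr >= bh || cc < 0 || cc >= bw) continue;
        if (vis[(size_t)rr * bw + cc]) continue;
        if (lab(minr[i] + rr, minc[i] + cc) == i + 1) continue;
        vis[(size_t)rr * bw + cc] = 1;
        stack.push_back(std::make_pair(rr, cc));
      }
    }
    int holes = 0;
    for (int r = 0; r < bh; ++r)
      for (int c = 0; c < bw; ++c)
        if (!vis[(size_t)r * bw + c] && lab(minr[i] + r, minc[i] + c) != i + 1) ++holes;
    nholes[i] = holes;
  }
  IntegerVector label(nlab);
  NumericVector cx(nlab), cy(nlab);
  for (int i = 0; i < nlab; ++i) {
    label[i] = i + 1;
    cx[i] = sumc[i] / npix[i] + 1.0;  // 1-based pixel-centre coordinates
    cy[i] = sumr[i] / npix[i] + 1.0;
  }
  return DataFrame::create(
      _["label"] = label, _["n_pixels"] = npix, _["n_hole_pixels"] = nholes,
      _["centroid_x"] = cx, _["centroid_y"] = cy,
      _["bbox_min_x"] = minc + 1, _["bbox_min_y"] = minr + 1,
      _["bbox_max_x"] = maxc + 1, _["bbox_max_y"] = maxr + 1,
      _["touches_edge"] = edge,
      _["n_axial"] = na, _["n_diagonal"] = nd, _["n_corners"] = nc);
}
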