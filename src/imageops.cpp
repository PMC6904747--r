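// Low-level raster primitives: separable convolution, connected-component
// labeling, 3x3 binary morphology, Zhang-Suen thinning with staircase pruning,
// exhaustive block-matching flow, and bilinear warping/resizing.
// No installed R package provides these (no EBImage/imager in the stack),
// so they are implemented here once and shared by every pipeline stage.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

// reflect-101 fold of index i into [0, n-1]; robust to kernels wider than the image
static inline int fold_reflect(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * (n - 1);
  i = i % period;
  if (i < 0) i += period;
  return (i < n) ? i : period - i;
}

// Separable 2-D convolution with an odd-length 1-D kernel applied along rows
// then columns. border: "reflect" (mirror, no edge repeat) or "zero".
// [[Rcpp::export(name = ".cf_sep_conv2")]]
NumericMatrix cf_sep_conv2(const NumericMatrix& img, const NumericVector& kernel,
                           const std::string& border) {
  const int nr = img.nrow(), nc = img.ncol();
  const int klen = kernel.size();
  if (klen % 2 == 0) stop("kernel length must be odd");
  const int kh = klen / 2;
  const bool zero = (border == "zero");
  if (!zero && border != "reflect") stop("border must be 'reflect' or 'zero'");

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // pass 1: along columns (vertical, i.e. over rows)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int k = -kh; k <= kh; ++k) {
        int rr = r + k;
        if (zero) {
          if (rr < 0 || rr >= nr) continue;
        } else {
          rr = fold_reflect(rr, nr);
        }
        acc += img(rr, c) * kernel[k + kh];
      }
      tmp(r, c) = acc;
    }
  }
  // pass 2: along rows (horizontal, over columns)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int k = -kh; k <= kh; ++k) {
        int cc = c + k;
        if (zero) {
          if (cc < 0 || cc >= nc) continue;
        } else {
          cc = fold_reflect(cc, nc);
        }
        acc += tmp(r, cc) * kernel[k + kh];
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// Connected-component labeling of a logical mask. Labels are assigned in
// raster order of each component's first-encountered pixel, starting at 1.
// [[Rcpp::export(name = ".cf_label_components")]]
IntegerMatrix cf_label_components(const LogicalMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int,int> > stack;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1,  0,  1,-1, 1,-1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = { 0,-1, 1, 0};
  const int nn = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  int next = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back();
        stack.pop_back();
        for (int k = 0; k < nn; ++k) {
          int rr = p.first + dr[k], cc = p.second + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// 3x3 square-element binary erosion/dilation; pixels outside the image are
// treated as background.
// [[Rcpp::export(name = ".cf_morph3")]]
LogicalMatrix cf_morph3(const LogicalMatrix& mask, const std::string& op, int iterations) {
  const bool erode = (op == "erode");
  if (!erode && op != "dilate") stop("op must be 'erode' or 'dilate'");
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix cur = clone(mask);
  for (int it = 0; it < iterations; ++it) {
    LogicalMatrix nxt(nr, nc);
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        bool v = erode;
        for (int dr = -1; dr <= 1 && (erode ? v : !v); ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            int rr = r + dr, cc = c + dc;
            bool px = (rr >= 0 && rr < nr && cc >= 0 && cc < nc) ? (bool)cur(rr, cc) : false;
            if (erode) { if (!px) { v = false; break; } }
            else       { if (px)  { v = true;  break; } }
          }
        }
        nxt(r, c) = v;
      }
    }
    cur = nxt;
  }
  return cur;
}

static inline int px(const LogicalMatrix& m, int r, int c) {
  if (r < 0 || r >= m.nrow() || c < 0 || c >= m.ncol()) return 0;
  return m(r, c) ? 1 : 0;
}

// Hilditch connectivity number: 1 means deleting the pixel preserves topology.
static int hilditch_xh(const LogicalMatrix& m, int r, int c) {
  // neighbors in order P2..P9 = N, NE, E, SE, S, SW, W, NW (clockwise)
  int p[8];
  p[0] = px(m, r - 1, c);     p[1] = px(m, r - 1, c + 1);
  p[2] = px(m, r,     c + 1); p[3] = px(m, r + 1, c + 1);
  p[4] = px(m, r + 1, c);     p[5] = px(m, r + 1, c - 1);
  p[6] = px(m, r,     c - 1); p[7] = px(m, r - 1, c - 1);
  int xh = 0;
  for (int i = 0; i < 4; ++i) {
    int a = p[2 * i], b = p[2 * i + 1], d = p[(2 * i + 2) % 8];
    if (a == 0 && (b == 1 || d == 1)) ++xh;
  }
  return xh;
}

// Zhang-Suen two-subiteration thinning followed by a staircase-pruning pass
// that removes topology-preserving corners of residual 2x2 foreground blocks.
// Plain Zhang-Suen deletes an isolated 2x2 square entirely in one parallel
// subiteration; a per-component guard keeps the last pixel of each original
// 8-connected component so small objects shrink to a point instead of
// vanishing.
// [[Rcpp::export(name = ".cf_zhang_suen")]]
LogicalMatrix cf_zhang_suen(const LogicalMatrix& mask, bool prune) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix m = clone(mask);
  IntegerMatrix comp = cf_label_components(mask, 8);
  int ncomp = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (comp(r, c) > ncomp) ncomp = comp(r, c);
  std::vector<int> remain(ncomp + 1, 0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (comp(r, c) > 0) ++remain[comp(r, c)];
  bool changed = true;
  std::vector<std::pair<int,int> > kill;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!m(r, c)) continue;
          int p2 = px(m, r - 1, c),     p3 = px(m, r - 1, c + 1);
          int p4 = px(m, r,     c + 1), p5 = px(m, r + 1, c + 1);
          int p6 = px(m, r + 1, c),     p7 = px(m, r + 1, c - 1);
          int p8 = px(m, r,     c - 1), p9 = px(m, r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int A = 0;
          for (int i = 0; i < 8; ++i) if (seq[i] == 0 && seq[i + 1] == 1) ++A;
          if (A != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      for (size_t i = 0; i < kill.size(); ++i) {
        int lab = comp(kill[i].first, kill[i].second);
        if (remain[lab] <= 1) continue;   // never erase a whole component
        m(kill[i].first, kill[i].second) = false;
        --remain[lab];
        changed = true;
      }
    }
  }
  if (prune) {
    // remove simple pixels belonging to a 2x2 all-foreground block
    bool again = true;
    int guard = 0;
    while (again && guard++ < 8) {
      again = false;
      for (int r = 0; r < nr - 1; ++r) {
        for (int c = 0; c < nc - 1; ++c) {
          if (m(r, c) && m(r, c + 1) && m(r + 1, c) && m(r + 1, c + 1)) {
            const int cr[4] = {r, r, r + 1, r + 1};
            const int cc[4] = {c, c + 1, c, c + 1};
            for (int k = 0; k < 4; ++k) {
              if (hilditch_xh(m, cr[k], cc[k]) == 1) {
                m(cr[k], cc[k]) = false;
                again = true;
                break;
              }
            }
          }
        }
      }
    }
  }
  return m;
}

// Exhaustive integer block matching: for every pixel, the displacement in
// [-radius, radius]^2 minimising mean absolute block difference. Candidates are
// scanned in order of increasing magnitude so an untranslated scene yields an
// exactly zero field; a strictly smaller cost is required to move off (0, 0).
// [[Rcpp::export(name = ".cf_block_flow")]]
List cf_block_flow(const NumericMatrix& a, const NumericMatrix& b,
                   int half_block, int radius) {
  const int nr = a.nrow(), nc = a.ncol();
  if (b.nrow() != nr || b.ncol() != nc) stop("frame shapes differ");
  NumericMatrix u(nr, nc), v(nr, nc);

  // candidate displacements sorted by magnitude, then (dv, du)
  std::vector<std::pair<int,int> > cand;
  for (int dv = -radius; dv <= radius; ++dv)
    for (int du = -radius; du <= radius; ++du)
      cand.push_back(std::make_pair(dv, du));
  for (size_t i = 1; i < cand.size(); ++i) {
    std::pair<int,int> key = cand[i];
    double km = key.first * key.first + key.second * key.second;
    size_t j = i;
    while (j > 0) {
      double m0 = cand[j-1].first * cand[j-1].first + cand[j-1].second * cand[j-1].second;
      if (m0 > km || (m0 == km && (cand[j-1].first > key.first ||
          (cand[j-1].first == key.first && cand[j-1].second > key.second)))) {
        cand[j] = cand[j-1]; --j;
      } else break;
    }
    cand[j] = key;
  }

  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double best = R_PosInf;
      int bdv = 0, bdu = 0;
      for (size_t k = 0; k < cand.size(); ++k) {
        const int dv = cand[k].first, du = cand[k].second;
        double cost = 0.0;
        int n = 0;
        for (int br = -half_block; br <= half_block; ++br) {
          int r1 = r + br;
          if (r1 < 0 || r1 >= nr) continue;
          int r2 = r1 + dv;
          if (r2 < 0 || r2 >= nr) continue;
          for (int bc = -half_block; bc <= half_block; ++bc) {
            int c1 = c + bc;
            if (c1 < 0 || c1 >= nc) continue;
            int c2 = c1 + du;
            if (c2 < 0 || c2 >= nc) continue;
            cost += std::abs(a(r1, c1) - b(r2, c2));
            ++n;
          }
        }
        if (n == 0) continue;
        cost /= n;
        if (cost < best - 1e-12) { best = cost; bdv = dv; bdu = du; }
      }
      v(r, c) = bdv;
      u(r, c) = bdu;
    }
  }
  return List::create(_["u"] = u, _["v"] = v);
}

// Bilinear sampling of img at (r + v, c + u); out-of-range samples clamp to
// the nearest edge pixel.
// [[Rcpp::export(name = ".cf_bilinear_warp")]]
NumericMatrix cf_bilinear_warp(const NumericMatrix& img, const NumericMatrix& u,
                               const NumericMatrix& v) {
  const int nr = img.nrow(), nc = img.ncol();
  if (u.nrow() != nr || u.ncol() != nc || v.nrow() != nr || v.ncol() != nc)
    stop("flow field shape differs from image");
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double sr = r + v(r, c), sc = c + u(r, c);
      if (sr < 0) sr = 0; if (sr > nr - 1) sr = nr - 1;
      if (sc < 0) sc = 0; if (sc > nc - 1) sc = nc - 1;
      int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      int r1 = (r0 + 1 < nr) ? r0 + 1 : r0;
      int c1 = (c0 + 1 < nc) ? c0 + 1 : c0;
      double fr = sr - r0, fc = sc - c0;
      out(r, c) = (1 - fr) * ((1 - fc) * img(r0, c0) + fc * img(r0, c1)) +
                  fr       * ((1 - fc) * img(r1, c0) + fc * img(r1, c1));
    }
  }
  return out;
}

// Bilinear resize to (nrow_out, ncol_out) with corner-aligned sampling.
// [[Rcpp::export(name = ".cf_resize_bilinear")]]
NumericMatrix cf_resize_bilinear(const NumericMatrix& img, int nrow_out, int ncol_out) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nrow_out, ncol_out);
  double rs = (nrow_out > 1) ? (double)(nr - 1) / (nrow_out - 1) : 0.0;
  double cs = (ncol_out > 1) ? (double)(nc - 1) / (ncol_out - 1) : 0.0;
  for (int r = 0; r < nrow_out; ++r) {
    double sr = r * rs;
    int r0 = (int)std::floor(sr);
    int r1 = (r0 + 1 < nr) ? r0 + 1 : r0;
    double fr = sr - r0;
    for (int c = 0; c < ncol_out; ++c) {
      double sc = c * cs;
      int c0 = (int)std::floor(sc);
      int c1 = (c0 + 1 < nc) ? c0 + 1 : c0;
      double fc = sc - c0;
      out(r, c) = (1 - fr) * ((1 - fc) * img(r0, c0) + fc * img(r0, c1)) +
                  fr       * ((1 - fc) * img(r1, c0) + fc * img(r1, c1));
    }
  }
  return out;
}
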