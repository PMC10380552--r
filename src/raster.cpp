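// Raster primitives shared by the segmentation and trait modules.
// All exported coordinates are 1-based (row, col) to match the R side.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DR4[4] = {-1, 0, 0, 1};
static const int DC4[4] = {0, -1, 1, 0};

// [[Rcpp::export]]
List cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix labels(H, W);
  int count = 0;
  const int* dr = (connectivity == 8) ? DR8 : DR4;
  const int* dc = (connectivity == 8) ? DC8 : DC4;
  const int nn = (connectivity == 8) ? 8 : 4;
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || labels(r, c) != 0) continue;
      ++count;
      stack.clear();
      stack.push_back(r + c * H);
      labels(r, c) = count;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % H, cc = idx / H;
        for (int k = 0; k < nn; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (mask(r2, c2) && labels(r2, c2) == 0) {
            labels(r2, c2) = count;
            stack.push_back(r2 + c2 * H);
          }
        }
      }
    }
  }
  return List::create(_["count"] = count, _["labels"] = labels);
}

// Moore-neighbor boundary trace of the single foreground component.
// Returns the ordered closed boundary, one row per pixel, 1-based.
// [[Rcpp::export]]
IntegerMatrix cpp_moore_boundary(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  int sr = -1, sc = -1;
  for (int r = 0; r < H && sr < 0; ++r)
    for (int c = 0; c < W; ++c)
      if (mask(r, c)) { sr = r; sc = c; break; }
  if (sr < 0) stop("mask is empty");

  // clockwise Moore neighborhood starting from "west"
  static const int mr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  static const int mc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};

  std::vector<int> rows, cols;
  rows.push_back(sr); cols.push_back(sc);

  // single-pixel component
  bool lone = true;
  for (int k = 0; k < 8 && lone; ++k) {
    int r2 = sr + DR8[k], c2 = sc + DC8[k];
    if (r2 >= 0 && r2 < H && c2 >= 0 && c2 < W && mask(r2, c2)) lone = false;
  }
  if (lone) {
    IntegerMatrix out(1, 2);
    out(0, 0) = sr + 1; out(0, 1) = sc + 1;
    return out;
  }

  int pr = sr, pc = sc;   // current pixel
  int bdir = 0;           // index into the moore order of the backtrack pixel
  long cap = 4L * H * W + 8;
  int first_next_r = -1, first_next_c = -1;
  while (cap-- > 0) {
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int dir = (bdir + k) % 8;
      int r2 = pr + mr[dir], c2 = pc + mc[dir];
      if (r2 >= 0 && r2 < H && c2 >= 0 && c2 < W && mask(r2, c2)) { found = dir; break; }
    }
    if (found < 0) break; // isolated (handled above), defensive
    int nr = pr + mr[found], nc = pc + mc[found];
    // stop when we step onto the start pixel the same way we first left it
    if (first_next_r < 0) { first_next_r = nr; first_next_c = nc; }
    else if (pr == sr && pc == sc && nr == first_next_r && nc == first_next_c) break;
    if (!(nr == sr && nc == sc)) { rows.push_back(nr); cols.push_back(nc); }
    else {
      // re-entered start; keep looping until termination condition above fires
    }
    // new backtrack = the neighbor just before the found one, relative to new pixel
    int prev_dir = (found + 8 - 1) % 8;
    int br = pr + mr[prev_dir], bc = pc + mc[prev_dir];
    pr = nr; pc = nc;
    // direction from new pixel back to b
    int db = -1;
    for (int k = 0; k < 8; ++k)
      if (pr + mr[k] == br && pc + mc[k] == bc) { db = k; break; }
    bdir = (db >= 0) ? db : 0;
    if (pr == sr && pc == sc && (int)rows.size() > 1) {
      // next iteration will test the stopping criterion
    }
  }

  int n = rows.size();
  // enforce counter-clockwise orientation as seen on screen (y axis down):
  // shoelace with x = col, y = row is positive for clockwise-on-screen walks.
  double area2 = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    area2 += (double)cols[i] * rows[j] - (double)cols[j] * rows[i];
  }
  IntegerMatrix out(n, 2);
  if (area2 > 0) {
    for (int i = 0; i < n; ++i) {
      out(i, 0) = rows[n - 1 - i] + 1; out(i, 1) = cols[n - 1 - i] + 1;
    }
    // keep the start pixel first after reversal
    // rotate so original start stays at index 0
    IntegerMatrix rot(n, 2);
    rot(0, 0) = sr + 1; rot(0, 1) = sc + 1;
    // find start in out
    int s = 0;
    for (int i = 0; i < n; ++i) if (out(i,0) == sr + 1 && out(i,1) == sc + 1) { s = i; break; }
    for (int i = 0; i < n; ++i) {
      rot(i, 0) = out((s + i) % n, 0);
      rot(i, 1) = out((s + i) % n, 1);
    }
    return rot;
  }
  for (int i = 0; i < n; ++i) { out(i, 0) = rows[i] + 1; out(i, 1) = cols[i] + 1; }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_bresenham(int r0, int c0, int r1, int c1) {
  std::vector<int> rows, cols;
  int dc = std::abs(c1 - c0), sc = (c0 < c1) ? 1 : -1;
  int dr = -std::abs(r1 - r0), sr = (r0 < r1) ? 1 : -1;
  int err = dc + dr;
  int r = r0, c = c0;
  while (true) {
    rows.push_back(r); cols.push_back(c);
    if (r == r1 && c == c1) break;
    int e2 = 2 * err;
    if (e2 >= dr) { err += dr; c += sc; }
    if (e2 <= dc) { err += dc; r += sr; }
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) { out(i, 0) = rows[i]; out(i, 1) = cols[i]; }
  return out;
}

// Fill a closed pixel contour: rasterize the boundary chain (Bresenham between
// consecutive vertices), then flood the background from the image border;
// everything not reached is foreground (boundary included).
// [[Rcpp::export]]
LogicalMatrix cpp_fill_contour(const IntegerMatrix& pts, int H, int W) {
  LogicalMatrix boundary(H, W);
  const int n = pts.nrow();
  for (int i = 0; i < n; ++i) {
    int r0 = pts(i, 0) - 1, c0 = pts(i, 1) - 1;
    int j = (i + 1) % n;
    int r1 = pts(j, 0) - 1, c1 = pts(j, 1) - 1;
    IntegerMatrix seg = cpp_bresenham(r0, c0, r1, c1);
    for (int k = 0; k < seg.nrow(); ++k) {
      int r = seg(k, 0), c = seg(k, 1);
      if (r >= 0 && r < H && c >= 0 && c < W) boundary(r, c) = true;
    }
  }
  LogicalMatrix outside(H, W);
  std::queue<int> q;
  for (int c = 0; c < W; ++c) {
    for (int r : {0, H - 1}) {
      if (!boundary(r, c) && !outside(r, c)) { outside(r, c) = true; q.push(r + c * H); }
    }
  }
  for (int r = 0; r < H; ++r) {
    for (int c : {0, W - 1}) {
      if (!boundary(r, c) && !outside(r, c)) { outside(r, c) = true; q.push(r + c * H); }
    }
  }
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int r = idx % H, c = idx / H;
    for (int k = 0; k < 4; ++k) {
      int r2 = r + DR4[k], c2 = c + DC4[k];
      if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
      if (!boundary(r2, c2) && !outside(r2, c2)) { outside(r2, c2) = true; q.push(r2 + c2 * H); }
    }
  }
  LogicalMatrix fill(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      fill(r, c) = !outside(r, c);
  return fill;
}

// Zhang-Suen thinning to a 1-px skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_skeletonize(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<char> img(H * W, 0);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      img[r + c * H] = mask(r, c) ? 1 : 0;
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= H || c < 0 || c >= W) return 0;
    return img[r + c * H];
  };
  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          if (!at(r, c)) continue;
          int p2 = at(r - 1, c), p3 = at(r - 1, c + 1), p4 = at(r, c + 1),
              p5 = at(r + 1, c + 1), p6 = at(r + 1, c), p7 = at(r + 1, c - 1),
              p8 = at(r, c - 1), p9 = at(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) + (p4 == 0 && p5 == 1) +
                  (p5 == 0 && p6 == 1) + (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(r + c * H);
        }
      }
      for (int idx : kill) img[idx] = 0;
      if (!kill.empty()) changed = true;
    }
  }
  LogicalMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      out(r, c) = img[r + c * H] != 0;
  return out;
}

// Extract size x size x C tiles centered (center pixel at 1-based index
// size/2 + 1) at each given (row, col); out-of-bounds filled with `fill`.
// Returns list(tiles = [S,S,C,n], pad = [S,S,n]).
// [[Rcpp::export]]
List cpp_extract_tiles(const NumericVector& image, const IntegerMatrix& centers,
                       int size, double fill) {
  IntegerVector dims = image.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2];
  const int n = centers.nrow();
  const int half = size / 2;
  NumericVector tiles((R_xlen_t)size * size * C * n);
  tiles.attr("dim") = IntegerVector::create(size, size, C, n);
  LogicalVector pad(Dimension(size, size, n));
  const double* src = image.begin();
  double* dst = tiles.begin();
  for (int s = 0; s < n; ++s) {
    int cr = centers(s, 0) - 1, cc = centers(s, 1) - 1;
    for (int ch = 0; ch < C; ++ch) {
      for (int j = 0; j < size; ++j) {
        int c2 = cc + j - half;
        for (int i = 0; i < size; ++i) {
          int r2 = cr + i - half;
          double v;
          bool out = (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W);
          v = out ? fill : src[r2 + (size_t)c2 * H + (size_t)ch * H * W];
          dst[i + (size_t)j * size + (size_t)ch * size * size +
              (size_t)s * size * size * C] = v;
          if (ch == 0) pad[i + (size_t)j * size + (size_t)s * size * size] = out;
        }
      }
    }
  }
  return List::create(_["tiles"] = tiles, _["pad"] = pad);
}

// One wave of region growing: add 3x3 probability patches into the
// accumulator, mark centers as visited, and return the next wave of centers
// (8-neighbors with vein probability > thresh, inside leaf mask, never
// queued before). `queued` and `visited` are modified in place.
// [[Rcpp::export]]
IntegerMatrix cpp_grow_update(NumericMatrix prob_sum, NumericMatrix visit_count,
                              LogicalMatrix queued, const LogicalMatrix& leaf_mask,
                              const IntegerMatrix& centers, const NumericMatrix& probs,
                              double thresh) {
  const int H = prob_sum.nrow(), W = prob_sum.ncol();
  const int n = centers.nrow();
  std::vector<int> nr, nc;
  for (int s = 0; s < n; ++s) {
    int cr = centers(s, 0) - 1, cc = centers(s, 1) - 1;
    int k = 0;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        int r2 = cr + dr, c2 = cc + dc;
        double p = probs(k, s);
        if (r2 >= 0 && r2 < H && c2 >= 0 && c2 < W) {
          prob_sum(r2, c2) += p;
          visit_count(r2, c2) += 1.0;
          if ((dr != 0 || dc != 0) && p > thresh && leaf_mask(r2, c2) && !queued(r2, c2)) {
            queued(r2, c2) = true;
            nr.push_back(r2 + 1); nc.push_back(c2 + 1);
          }
        }
        ++k;
      }
    }
  }
  IntegerMatrix out(nr.size(), 2);
  for (size_t i = 0; i < nr.size(); ++i) { out(i, 0) = nr[i]; out(i, 1) = nc[i]; }
  return out;
}

// Add full-tile probability maps into an accumulator at given tile centers,
// skipping out-of-bounds pixels. probs is [S, S, n].
// [[Rcpp::export]]
void cpp_accumulate_tiles(NumericMatrix prob_sum, NumericMatrix visit_count,
                          const IntegerMatrix& centers, const NumericVector& probs,
                          int size) {
  const int H = prob_sum.nrow(), W = prob_sum.ncol();
  const int n = centers.nrow();
  const int half = size / 2;
  const double* p = probs.begin();
  for (int s = 0; s < n; ++s) {
    int cr = centers(s, 0) - 1, cc = centers(s, 1) - 1;
    for (int j = 0; j < size; ++j) {
      int c2 = cc + j - half;
      if (c2 < 0 || c2 >= W) continue;
      for (int i = 0; i < size; ++i) {
        int r2 = cr + i - half;
        if (r2 < 0 || r2 >= H) continue;
        prob_sum(r2, c2) += p[i + (size_t)j * size + (size_t)s * size * size];
        visit_count(r2, c2) += 1.0;
      }
    }
  }
}
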