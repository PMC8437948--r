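#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// SLIC superpixels on CIE-Lab planes.  Distance follows
// d = d_lab + (compactness / S) * d_xy with Euclidean component distances,
// S the seed grid interval.  Seeds start on a regular grid, perturbed to
// the lowest-gradient position in a 3x3 neighbourhood; assignment searches
// a 2S x 2S window around each centre.  Returns a 1-based label matrix.
// [[Rcpp::export]]
IntegerMatrix slic_assign_cpp(NumericMatrix L, NumericMatrix A, NumericMatrix B,
                              int n_superpixels, double compactness, int iters) {
  const int H = L.nrow(), W = L.ncol();
  const double N = (double)H * W;
  const double S = std::sqrt(N / n_superpixels);
  int ny = std::max(1, (int)std::lround(H / S));
  int nx = std::max(1, (int)std::lround(W / S));
  const int K = ny * nx;

  std::vector<double> cy(K), cx(K), cL(K), cA(K), cB(K);
  int k = 0;
  for (int gy = 0; gy < ny; ++gy) {
    for (int gx = 0; gx < nx; ++gx, ++k) {
      double y0 = (gy + 0.5) * H / ny, x0 = (gx + 0.5) * W / nx;
      int yi = std::min(H - 1, std::max(0, (int)y0));
      int xi = std::min(W - 1, std::max(0, (int)x0));
      // move seed to the lowest-gradient pixel in a 3x3 window
      double best = R_PosInf; int by = yi, bx = xi;
      for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
        int y = yi + dy, x = xi + dx;
        if (y < 1 || y >= H - 1 || x < 1 || x >= W - 1) continue;
        double gyv = 0, gxv = 0;
        gyv += std::pow(L(y + 1, x) - L(y - 1, x), 2) +
               std::pow(A(y + 1, x) - A(y - 1, x), 2) +
               std::pow(B(y + 1, x) - B(y - 1, x), 2);
        gxv += std::pow(L(y, x + 1) - L(y, x - 1), 2) +
               std::pow(A(y, x + 1) - A(y, x - 1), 2) +
               std::pow(B(y, x + 1) - B(y, x - 1), 2);
        if (gyv + gxv < best) { best = gyv + gxv; by = y; bx = x; }
      }
      cy[k] = by; cx[k] = bx; cL[k] = L(by, bx); cA[k] = A(by, bx); cB[k] = B(by, bx);
    }
  }

  IntegerMatrix lab(H, W);
  NumericMatrix dist(H, W);
  const double wxy = compactness / S;
  const int win = (int)std::ceil(2.0 * S);

  for (int it = 0; it < iters; ++it) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int c = 0; c < K; ++c) {
      int y0 = std::max(0, (int)cy[c] - win), y1 = std::min(H - 1, (int)cy[c] + win);
      int x0 = std::max(0, (int)cx[c] - win), x1 = std::min(W - 1, (int)cx[c] + win);
      for (int x = x0; x <= x1; ++x) {
        for (int y = y0; y <= y1; ++y) {
          double dl = L(y, x) - cL[c], da = A(y, x) - cA[c], db = B(y, x) - cB[c];
          double dy = y - cy[c], dx = x - cx[c];
          double d = std::sqrt(dl * dl + da * da + db * db) +
                     wxy * std::sqrt(dy * dy + dx * dx);
          if (d < dist(y, x)) { dist(y, x) = d; lab(y, x) = c + 1; }
        }
      }
    }
    // pixels outside every search window (rare): nearest centre wins
    for (int x = 0; x < W; ++x) for (int y = 0; y < H; ++y) {
      if (lab(y, x) > 0) continue;
      double best = R_PosInf; int bc = 1;
      for (int c = 0; c < K; ++c) {
        double dy = y - cy[c], dx = x - cx[c];
        double d = dy * dy + dx * dx;
        if (d < best) { best = d; bc = c + 1; }
      }
      lab(y, x) = bc;
    }
    // recompute centres
    std::vector<double> sy(K, 0), sx(K, 0), sL(K, 0), sA(K, 0), sB(K, 0), cnt(K, 0);
    for (int x = 0; x < W; ++x) for (int y = 0; y < H; ++y) {
      int c = lab(y, x) - 1;
      if (c < 0) continue;
      sy[c] += y; sx[c] += x; sL[c] += L(y, x); sA[c] += A(y, x); sB[c] += B(y, x);
      cnt[c] += 1;
    }
    for (int c = 0; c < K; ++c) if (cnt[c] > 0) {
      cy[c] = sy[c] / cnt[c]; cx[c] = sx[c] / cnt[c];
      cL[c] = sL[c] / cnt[c]; cA[c] = sA[c] / cnt[c]; cB[c] = sB[c] / cnt[c];
    }
  }
  return lab;
}

// Enforce connectivity of a label map (classic SLIC post-processing):
// components are relabelled in raster order; any component smaller than
// min_size is absorbed into the most recently finalised adjacent
// component.  Returns labels compacted to 1..K'.
// [[Rcpp::export]]
IntegerMatrix slic_connectivity_cpp(IntegerMatrix lab, int min_size) {
  const int H = lab.nrow(), W = lab.ncol();
  IntegerMatrix out(H, W);
  std::fill(out.begin(), out.end(), -1);
  const int dy[4] = {-1, 1, 0, 0}, dx[4] = {0, 0, -1, 1};
  int count = 0;
  std::vector<std::pair<int,int> > comp;
  for (int y = 0; y < H; ++y) for (int x = 0; x < W; ++x) {
    if (out(y, x) >= 0) continue;
    // adjacent already-finalised label (fallback for tiny components)
    int adj = 0;
    for (int d = 0; d < 4; ++d) {
      int yy = y + dy[d], xx = x + dx[d];
      if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
      if (out(yy, xx) >= 0) adj = out(yy, xx);
    }
    comp.clear();
    std::queue<std::pair<int,int> > q;
    q.push(std::make_pair(y, x));
    out(y, x) = count;
    while (!q.empty()) {
      std::pair<int,int> p = q.front(); q.pop();
      comp.push_back(p);
      for (int d = 0; d < 4; ++d) {
        int yy = p.first + dy[d], xx = p.second + dx[d];
        if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
        if (out(yy, xx) < 0 && lab(yy, xx) == lab(y, x)) {
          out(yy, xx) = count;
          q.push(std::make_pair(yy, xx));
        }
      }
    }
    if ((int)comp.size() < min_size && count > 0) {
      for (size_t i = 0; i < comp.size(); ++i)
        out(comp[i].first, comp[i].second) = adj;
    } else {
      ++count;
    }
  }
  // compact to 1..K (some ids may have been absorbed entirely)
  std::vector<int> seen(count, 0);
  for (int x = 0; x < W; ++x) for (int y = 0; y < H; ++y) seen[out(y, x)] = 1;
  std::vector<int> newid(count, 0);
  int K = 0;
  for (int c = 0; c < count; ++c) if (seen[c]) newid[c] = ++K;
  for (int x = 0; x < W; ++x) for (int y = 0; y < H; ++y)
    out(y, x) = newid[out(y, x)];
  return out;
}

// Directed Hausdorff helper: symmetric Hausdorff distance between two
// point sets given as coordinate vectors, with early termination.
static double directed_hd(const NumericVector& ax, const NumericVector& ay,
                          const NumericVector& bx, const NumericVector& by) {
  double hmax = 0.0;
  const int na = ax.size(), nb = bx.size();
  for (int i = 0; i < na; ++i) {
    double dmin = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double dx = ax[i] - bx[j], dy = ay[i] - by[j];
      double d = dx * dx + dy * dy;
      if (d < dmin) {
        dmin = d;
        if (dmin <= hmax) break;  // cannot raise the running max
      }
    }
    if (dmin > hmax) hmax = dmin;
  }
  return std::sqrt(hmax);
}

// [[Rcpp::export]]
double hausdorff_cpp(NumericVector ax, NumericVector ay,
                     NumericVector bx, NumericVector by) {
  return std::max(directed_hd(ax, ay, bx, by), directed_hd(bx, by, ax, ay));
}
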