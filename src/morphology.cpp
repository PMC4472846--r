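// Low-level image kernels: grayscale ball opening (rolling-ball background),
// exact Euclidean distance transform, marker-based watershed, connected
// components, separable Gaussian blur, binary hole filling.
// Matrices are column-major (R layout): index (y, x) -> y + x * ny.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // symmetric reflection: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Reflect-pad by `pad` on all sides.
static std::vector<double> pad_reflect(const NumericMatrix& img, int pad,
                                       int& pny, int& pnx) {
  const int ny = img.nrow(), nx = img.ncol();
  pny = ny + 2 * pad;
  pnx = nx + 2 * pad;
  std::vector<double> out((size_t)pny * pnx);
  for (int x = 0; x < pnx; ++x) {
    const int sx = reflect_idx(x - pad, nx);
    for (int y = 0; y < pny; ++y) {
      out[(size_t)y + (size_t)x * pny] = img(reflect_idx(y - pad, ny), sx);
    }
  }
  return out;
}

// Rolling-ball background: grayscale opening with the ball height profile
// h(dy,dx) = sqrt(r^2 - dy^2 - dx^2) over dy^2 + dx^2 <= r^2.
// Erosion then dilation, reflect-padded so the crop has no rim artefacts.
// [[Rcpp::export]]
NumericMatrix cpp_rolling_background(NumericMatrix img, int radius) {
  const int ny = img.nrow(), nx = img.ncol(), r = radius;
  if (r < 1) stop("radius must be >= 1");

  // ball profile per row of the disk
  std::vector<int> span(2 * r + 1);
  std::vector< std::vector<double> > h(2 * r + 1);
  for (int dy = -r; dy <= r; ++dy) {
    const int s = (int)std::floor(std::sqrt((double)r * r - (double)dy * dy));
    span[dy + r] = s;
    h[dy + r].resize(2 * s + 1);
    for (int dx = -s; dx <= s; ++dx)
      h[dy + r][dx + s] = std::sqrt((double)r * r - (double)dy * dy - (double)dx * dx);
  }

  int pny, pnx;
  std::vector<double> P = pad_reflect(img, 2 * r, pny, pnx);

  // erosion on the domain padded by r (needed by the dilation pass)
  const int eny = ny + 2 * r, enx = nx + 2 * r;
  std::vector<double> E((size_t)eny * enx);
  for (int x = 0; x < enx; ++x) {
    for (int y = 0; y < eny; ++y) {
      // centre in P coordinates
      const int cy = y + r, cx = x + r;
      double m = std::numeric_limits<double>::infinity();
      for (int dy = -r; dy <= r; ++dy) {
        const int s = span[dy + r];
        const double* hp = h[dy + r].data();
        const double* col0 = P.data() + (size_t)(cx - s) * pny + (cy + dy);
        for (int k = 0; k <= 2 * s; ++k) {
          const double v = col0[(size_t)k * pny] - hp[k];
          if (v < m) m = v;
        }
      }
      E[(size_t)y + (size_t)x * eny] = m;
    }
  }

  NumericMatrix bg(ny, nx);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      const int cy = y + r, cx = x + r;  // in E coordinates
      double m = -std::numeric_limits<double>::infinity();
      for (int dy = -r; dy <= r; ++dy) {
        const int s = span[dy + r];
        const double* hp = h[dy + r].data();
        const double* col0 = E.data() + (size_t)(cx - s) * eny + (cy + dy);
        for (int k = 0; k <= 2 * s; ++k) {
          const double v = col0[(size_t)k * eny] + hp[k];
          if (v > m) m = v;
        }
      }
      bg(y, x) = m;
    }
  }
  return bg;
}

// Connected-component labelling, raster-order BFS. connectivity: 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  const int ny = mask.nrow(), nx = mask.ncol();
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  IntegerMatrix lab(ny, nx);
  std::vector<int> qy, qx;
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[4] = {-1, 0, 0, 1};
  const int dx4[4] = {0, -1, 1, 0};
  const int* DY = connectivity == 8 ? dy8 : dy4;
  const int* DX = connectivity == 8 ? dx8 : dx4;
  const int nnb = connectivity;
  int next = 0;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      ++next;
      lab(y, x) = next;
      qy.clear(); qx.clear();
      qy.push_back(y); qx.push_back(x);
      size_t head = 0;
      while (head < qy.size()) {
        const int cy = qy[head], cx = qx[head];
        ++head;
        for (int k = 0; k < nnb; ++k) {
          const int yy = cy + DY[k], xx = cx + DX[k];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          if (mask(yy, xx) && lab(yy, xx) == 0) {
            lab(yy, xx) = next;
            qy.push_back(yy); qx.push_back(xx);
          }
        }
      }
    }
  }
  return lab;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const double* f, double* d, int n, int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) / (2.0 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance transform: distance of each foreground pixel to
// the nearest background pixel (within the image; the border is not
// implicitly background). Background pixels get 0.
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask) {
  const int ny = mask.nrow(), nx = mask.ncol();
  const double INF = 1e20;
  std::vector<double> g((size_t)ny * nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      g[(size_t)y + (size_t)x * ny] = mask(y, x) ? INF : 0.0;

  const int nmax = std::max(ny, nx);
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // columns
  for (int x = 0; x < nx; ++x) {
    double* col = g.data() + (size_t)x * ny;
    for (int y = 0; y < ny; ++y) f[y] = col[y];
    dt1d(f.data(), d.data(), ny, v.data(), z.data());
    for (int y = 0; y < ny; ++y) col[y] = d[y];
  }
  // rows
  NumericMatrix out(ny, nx);
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) f[x] = g[(size_t)y + (size_t)x * ny];
    dt1d(f.data(), d.data(), nx, v.data(), z.data());
    for (int x = 0; x < nx; ++x) out(y, x) = std::sqrt(d[x]);
  }
  return out;
}

// Marker candidates on a distance map: descending flood with tolerance
// (h-maxima style merge), then greedy minimum-separation suppression.
// Returns an integer matrix with accepted marker pixels labelled 1..k.
// [[Rcpp::export]]
IntegerMatrix cpp_find_markers(NumericMatrix dist, LogicalMatrix mask,
                               double min_sep, double tol) {
  const int ny = dist.nrow(), nx = dist.ncol();
  std::vector<int> order;
  order.reserve(1024);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      if (mask(y, x) && dist(y, x) > 0) order.push_back(y + x * ny);
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    const double da = dist[a], db = dist[b];
    if (da != db) return da > db;
    return a < b;  // deterministic tie-break
  });

  std::vector<int> regid((size_t)ny * nx, 0);
  std::vector<int> peak_y, peak_x;
  std::vector<double> peak_d;
  std::vector<int> stack;
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int cur = 0;

  for (size_t i = 0; i < order.size(); ++i) {
    const int p = order[i];
    if (regid[p] != 0) continue;
    const double lvl = dist[p] - tol;
    // flood the region connected to p with dist > lvl over unclaimed pixels;
    // touching a pixel claimed by an earlier (higher) peak means p merges
    bool merged = false;
    ++cur;
    stack.clear();
    stack.push_back(p);
    regid[p] = cur;
    while (!stack.empty()) {
      const int q = stack.back();
      stack.pop_back();
      const int qy = q % ny, qx = q / ny;
      for (int k = 0; k < 8; ++k) {
        const int yy = qy + dy8[k], xx = qx + dx8[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        if (!mask(yy, xx)) continue;
        const int r = yy + xx * ny;
        if (dist[r] <= lvl) continue;
        if (regid[r] != 0) {
          if (regid[r] != cur) merged = true;
          continue;
        }
        regid[r] = cur;
        stack.push_back(r);
      }
    }
    if (!merged) {
      peak_y.push_back(p % ny);
      peak_x.push_back(p / ny);
      peak_d.push_back(dist[p]);
    }
  }

  // greedy suppression: peaks already in descending-dist order
  IntegerMatrix markers(ny, nx);
  std::vector<int> ay, ax;
  const double sep2 = min_sep * min_sep;
  int lab = 0;
  for (size_t i = 0; i < peak_y.size(); ++i) {
    bool ok = true;
    for (size_t j = 0; j < ay.size(); ++j) {
      const double dy = peak_y[i] - ay[j], dx = peak_x[i] - ax[j];
      if (dy * dy + dx * dx < sep2) { ok = false; break; }
    }
    if (ok) {
      ay.push_back(peak_y[i]);
      ax.push_back(peak_x[i]);
      markers(peak_y[i], peak_x[i]) = ++lab;
    }
  }
  return markers;
}

// Meyer's marker-based watershed flooding of -dist restricted to mask.
// Returns labels; watershed divide pixels are -1, background 0.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix dist, IntegerMatrix markers,
                            LogicalMatrix mask) {
  const int ny = dist.nrow(), nx = dist.ncol();
  IntegerMatrix lab(ny, nx);
  std::vector<char> inq((size_t)ny * nx, 0);
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  struct QE { double d; long seq; int idx; };
  struct Cmp {
    bool operator()(const QE& a, const QE& b) const {
      if (a.d != b.d) return a.d < b.d;   // pop highest distance first
      return a.seq > b.seq;               // FIFO among equals
    }
  };
  std::priority_queue<QE, std::vector<QE>, Cmp> pq;
  long seq = 0;

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      if (markers(y, x) > 0 && mask(y, x)) lab(y, x) = markers(y, x);

  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      if (lab(y, x) <= 0) continue;
      for (int k = 0; k < 8; ++k) {
        const int yy = y + dy8[k], xx = x + dx8[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        const int idx = yy + xx * ny;
        if (mask(yy, xx) && lab(yy, xx) == 0 && !inq[idx]) {
          inq[idx] = 1;
          pq.push(QE{dist(yy, xx), seq++, idx});
        }
      }
    }
  }

  while (!pq.empty()) {
    const QE e = pq.top();
    pq.pop();
    const int p = e.idx, py = p % ny, px = p / ny;
    if (lab(py, px) != 0) continue;
    int found = 0;
    bool conflict = false;
    for (int k = 0; k < 8; ++k) {
      const int yy = py + dy8[k], xx = px + dx8[k];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      const int l = lab(yy, xx);
      if (l > 0) {
        if (found == 0) found = l;
        else if (found != l) conflict = true;
      }
    }
    if (conflict || found == 0) {
      lab(py, px) = -1;  // divide line (or orphan next to divides only)
      continue;
    }
    lab(py, px) = found;
    for (int k = 0; k < 8; ++k) {
      const int yy = py + dy8[k], xx = px + dx8[k];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      const int idx = yy + xx * ny;
      if (mask(yy, xx) && lab(yy, xx) == 0 && !inq[idx]) {
        inq[idx] = 1;
        pq.push(QE{dist(yy, xx), seq++, idx});
      }
    }
  }
  return lab;
}

// Separable Gaussian blur, reflect boundary, kernel radius ceil(3 sigma).
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma) {
  const int ny = img.nrow(), nx = img.ncol();
  if (sigma <= 0) return clone(img);
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& kv : k) kv /= s;

  NumericMatrix tmp(ny, nx), out(ny, nx);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * img(reflect_idx(y + i, ny), x);
      tmp(y, x) = acc;
    }
  }
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * tmp(y, reflect_idx(x + i, nx));
      out(y, x) = acc;
    }
  }
  return out;
}

// Fill interior holes: background connected (4-conn) to the image border
// stays background, enclosed background becomes foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(LogicalMatrix mask) {
  const int ny = mask.nrow(), nx = mask.ncol();
  std::vector<char> outside((size_t)ny * nx, 0);
  std::vector<int> stack;
  auto push_bg = [&](int y, int x) {
    const int idx = y + x * ny;
    if (!mask(y, x) && !outside[idx]) {
      outside[idx] = 1;
      stack.push_back(idx);
    }
  };
  for (int x = 0; x < nx; ++x) { push_bg(0, x); push_bg(ny - 1, x); }
  for (int y = 0; y < ny; ++y) { push_bg(y, 0); push_bg(y, nx - 1); }
  const int dy4[4] = {-1, 0, 0, 1};
  const int dx4[4] = {0, -1, 1, 0};
  while (!stack.empty()) {
    const int p = stack.back();
    stack.pop_back();
    const int py = p % ny, px = p / ny;
    for (int kk = 0; kk < 4; ++kk) {
      const int yy = py + dy4[kk], xx = px + dx4[kk];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      push_bg(yy, xx);
    }
  }
  LogicalMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      out(y, x) = mask(y, x) || !outside[(size_t)y + (size_t)x * ny];
  return out;
}
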