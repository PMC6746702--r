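// Numerical kernels: batched 2-D convolution (im2col + GEMM), 2x2 max pooling,
// and Dijkstra shortest-path boundary delineation on a probability-map graph.
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dim4(const NumericVector& x, int* d) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// im2col for one sample with 'same' zero padding, stride 1.
// x: pointer to (H, W, C) slab, column-major R layout.
// col: K x (H*W) with K = kh*kw*C, row index ikh + kh*(ikw + kw*ic),
// column index r + H*c (matches R array flattening of the output plane).
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, arma::mat& col) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int K = kh * kw * C;
  col.zeros(K, (size_t)H * W);
  for (int ic = 0; ic < C; ++ic) {
    const double* plane = x + (size_t)ic * H * W;
    for (int ikw = 0; ikw < kw; ++ikw) {
      for (int ikh = 0; ikh < kh; ++ikh) {
        const int krow = ikh + kh * (ikw + kw * ic);
        // output pixel (r, c) reads input (r + ikh - ph, c + ikw - pw)
        const int roff = ikh - ph, coff = ikw - pw;
        const int c0 = std::max(0, -coff), c1 = std::min(W, W - coff);
        const int r0 = std::max(0, -roff), r1 = std::min(H, H - roff);
        for (int c = c0; c < c1; ++c) {
          const double* src = plane + (size_t)(c + coff) * H + roff;
          double* dst = col.memptr() + (size_t)(c) * H * K + krow;
          for (int r = r0; r < r1; ++r) dst[(size_t)r * K] = src[r];
        }
      }
    }
  }
}

// scatter-add transpose of im2col
static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, double* x) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int K = kh * kw * C;
  for (int ic = 0; ic < C; ++ic) {
    double* plane = x + (size_t)ic * H * W;
    for (int ikw = 0; ikw < kw; ++ikw) {
      for (int ikh = 0; ikh < kh; ++ikh) {
        const int krow = ikh + kh * (ikw + kw * ic);
        const int roff = ikh - ph, coff = ikw - pw;
        const int c0 = std::max(0, -coff), c1 = std::min(W, W - coff);
        const int r0 = std::max(0, -roff), r1 = std::min(H, H - roff);
        for (int c = c0; c < c1; ++c) {
          double* dst = plane + (size_t)(c + coff) * H + roff;
          const double* src = col.memptr() + (size_t)(c) * H * K + krow;
          for (int r = r0; r < r1; ++r) dst[r] += src[(size_t)r * K];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward(NumericVector x, NumericVector w, NumericVector b) {
  int dx[4]; get_dim4(x, dx);
  IntegerVector dw = w.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], F = dw[3];
  if (dw[2] != C) stop("channel mismatch between input and weights");
  const int K = kh * kw * C;
  arma::mat Wm(const_cast<double*>(w.begin()), K, F, false, true);
  arma::vec bv(const_cast<double*>(b.begin()), F, false, true);
  NumericVector y((size_t)H * W * F * N);
  y.attr("dim") = IntegerVector::create(H, W, F, N);
  arma::mat col;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, col);
    arma::mat out(y.begin() + (size_t)n * H * W * F, (size_t)H * W, F, false, true);
    out = col.t() * Wm;
    out.each_row() += bv.t();
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector dy) {
  int dx4[4]; get_dim4(x, dx4);
  IntegerVector dw4 = w.attr("dim");
  const int H = dx4[0], W = dx4[1], C = dx4[2], N = dx4[3];
  const int kh = dw4[0], kw = dw4[1], F = dw4[3];
  const int K = kh * kw * C;
  arma::mat Wm(const_cast<double*>(w.begin()), K, F, false, true);
  NumericVector dxv((size_t)H * W * C * N);
  dxv.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dwv((size_t)K * F);
  dwv.attr("dim") = IntegerVector::create(kh, kw, C, F);
  NumericVector dbv(F);
  arma::mat dWm(dwv.begin(), K, F, false, true);
  arma::vec db(dbv.begin(), F, false, true);
  arma::mat col, dcol;
  for (int n = 0; n < N; ++n) {
    arma::mat dYm(const_cast<double*>(dy.begin()) + (size_t)n * H * W * F,
                  (size_t)H * W, F, false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, col);
    dWm += col * dYm;
    db += arma::sum(dYm, 0).t();
    dcol = Wm * dYm.t();
    col2im(dcol, H, W, C, kh, kw, dxv.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(NumericVector x) {
  int d[4]; get_dim4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("max pooling needs even height and width");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N); // 0-based linear index into x
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int wc = 0; wc < Wo; ++wc)
        for (int hr = 0; hr < Ho; ++hr) {
          const size_t i00 = base + (size_t)(2 * wc) * H + 2 * hr;
          size_t best = i00; double bv = x[i00];
          const size_t cand[3] = {i00 + 1, i00 + (size_t)H, i00 + (size_t)H + 1};
          for (int k = 0; k < 3; ++k)
            if (x[cand[k]] > bv) { bv = x[cand[k]]; best = cand[k]; }
          y[o] = bv; idx[o] = (int)best; ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
NumericVector maxpool2_backward(NumericVector dy, IntegerVector idx,
                                IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// Dijkstra shortest path over a probability map. Vertices are pixels plus
// one probability-1 auxiliary column on each side of the image; directed
// edges run rightward to the horizontal / diagonal neighbours with weight
// 2 - (P_s + P_d) + w_min, and top-to-bottom within the auxiliary columns.
// Distances are computed from the source (top-left auxiliary vertex) and,
// on the reversed graph, from the sink (bottom-right auxiliary vertex); the
// returned path then greedily follows the optimal-path DAG preferring the
// smallest row, so equal-cost alternatives resolve deterministically to the
// upper path. Returns the 0-based path row in each real column.

struct BoundaryGraph {
  int H, W, WC;
  const Rcpp::NumericMatrix& P;
  double wmin;
  BoundaryGraph(const Rcpp::NumericMatrix& P_, double wmin_)
    : H(P_.nrow()), W(P_.ncol()), WC(P_.ncol() + 2), P(P_), wmin(wmin_) {}
  size_t vid(int r, int c) const { return (size_t)c * H + r; }
  double pv(int r, int c) const {
    return (c == 0 || c == WC - 1) ? 1.0 : P(r, c - 1);
  }
  double w(int r1, int c1, int r2, int c2) const {
    return 2.0 - (pv(r1, c1) + pv(r2, c2)) + wmin;
  }
  // neighbours of (r, c): rightward fan in ascending row order, then the
  // vertical auxiliary-column edge (reversed when forward = false)
  template <class F> void neighbours(int r, int c, bool forward, F f) const {
    if (forward) {
      if (c + 1 < WC)
        for (int dr = -1; dr <= 1; ++dr) {
          int rr = r + dr;
          if (rr >= 0 && rr < H) f(rr, c + 1, w(r, c, rr, c + 1));
        }
      if ((c == 0 || c == WC - 1) && r + 1 < H)
        f(r + 1, c, w(r, c, r + 1, c));
    } else {
      if (c > 0)
        for (int dr = -1; dr <= 1; ++dr) {
          int rr = r + dr;
          if (rr >= 0 && rr < H) f(rr, c - 1, w(rr, c - 1, r, c));
        }
      if ((c == 0 || c == WC - 1) && r > 0)
        f(r - 1, c, w(r - 1, c, r, c));
    }
  }
  std::vector<double> dijkstra(size_t start, bool forward) const {
    std::vector<double> dist((size_t)H * WC, R_PosInf);
    typedef std::pair<double, size_t> QE;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > q;
    dist[start] = 0.0;
    q.push(QE(0.0, start));
    while (!q.empty()) {
      QE top = q.top(); q.pop();
      const double d = top.first; const size_t u = top.second;
      if (d > dist[u]) continue;
      const int c = (int)(u / H), r = (int)(u % H);
      neighbours(r, c, forward, [&](int rr, int cc, double wt) {
        const size_t v = vid(rr, cc);
        if (d + wt < dist[v]) {
          dist[v] = d + wt;
          q.push(QE(dist[v], v));
        }
      });
    }
    return dist;
  }
};

// [[Rcpp::export(name = ".dijkstra_boundary")]]
IntegerVector dijkstra_boundary(NumericMatrix P, double wmin) {
  if (P.ncol() < 2) stop("probability map must have at least 2 columns");
  BoundaryGraph g(P, wmin);
  const size_t src = g.vid(0, 0), snk = g.vid(g.H - 1, g.WC - 1);
  std::vector<double> df = g.dijkstra(src, true);
  std::vector<double> db = g.dijkstra(snk, false);
  const double total = df[snk];
  if (!R_finite(total)) stop("graph search failed to reach the sink");
  const double tol = 1e-9 * (1.0 + std::abs(total));
  IntegerVector rows(g.W);
  size_t u = src;
  long guard = 0;
  while (u != snk) {
    if (++guard > (long)g.H * g.WC + 2) stop("path reconstruction failed");
    const int c = (int)(u / g.H), r = (int)(u % g.H);
    size_t next = snk; bool found = false;
    g.neighbours(r, c, true, [&](int rr, int cc, double wt) {
      if (found) return;
      const size_t v = g.vid(rr, cc);
      if (std::abs(df[u] + wt + db[v] - total) <= tol) {
        next = v; found = true;
      }
    });
    if (!found) stop("path reconstruction failed (no optimal successor)");
    u = next;
    const int cc = (int)(u / g.H);
    if (cc >= 1 && cc <= g.W) rows[cc - 1] = (int)(u % g.H);
  }
  return rows;
}
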