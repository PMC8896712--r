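#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Spatial hash for neighbour queries on scattered points.
struct CellHash {
  double cell;
  double x0, y0;
  std::unordered_map<long long, std::vector<int> > cells;

  CellHash(const NumericVector& px, const NumericVector& py, double cell_size)
      : cell(cell_size) {
    x0 = *std::min_element(px.begin(), px.end());
    y0 = *std::min_element(py.begin(), py.end());
    for (int i = 0; i < px.size(); ++i) {
      cells[key(px[i], py[i])].push_back(i);
    }
  }
  long long key(double x, double y) const {
    long long ix = (long long)std::floor((x - x0) / cell);
    long long iy = (long long)std::floor((y - y0) / cell);
    return ix * 2000003LL + iy;
  }
  // indices of points in cells overlapping the disc (x, y, r)
  void gather(double x, double y, double r, std::vector<int>& out) const {
    out.clear();
    long long ix0 = (long long)std::floor((x - r - x0) / cell);
    long long ix1 = (long long)std::floor((x + r - x0) / cell);
    long long iy0 = (long long)std::floor((y - r - y0) / cell);
    long long iy1 = (long long)std::floor((y + r - y0) / cell);
    for (long long ix = ix0; ix <= ix1; ++ix)
      for (long long iy = iy0; iy <= iy1; ++iy) {
        std::unordered_map<long long, std::vector<int> >::const_iterator it =
            cells.find(ix * 2000003LL + iy);
        if (it != cells.end())
          out.insert(out.end(), it->second.begin(), it->second.end());
      }
  }
};

// Solve the symmetric 3x3 system A b = rhs in place; returns false if A is
// numerically singular relative to its scale.
static bool solve3(double A[3][3], double rhs[3], double out[3]) {
  double M[3][4];
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) M[i][j] = A[i][j];
    M[i][3] = rhs[i];
  }
  double scale = 0.0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) scale = std::max(scale, std::fabs(M[i][j]));
  if (scale <= 0.0) return false;
  for (int c = 0; c < 3; ++c) {
    int piv = c;
    for (int r = c + 1; r < 3; ++r)
      if (std::fabs(M[r][c]) > std::fabs(M[piv][c])) piv = r;
    if (std::fabs(M[piv][c]) < 1e-12 * scale) return false;
    if (piv != c)
      for (int j = c; j < 4; ++j) std::swap(M[piv][j], M[c][j]);
    for (int r = c + 1; r < 3; ++r) {
      double f = M[r][c] / M[c][c];
      for (int j = c; j < 4; ++j) M[r][j] -= f * M[c][j];
    }
  }
  for (int i = 2; i >= 0; --i) {
    double s = M[i][3];
    for (int j = i + 1; j < 3; ++j) s -= M[i][j] * out[j];
    out[i] = s / M[i][i];
  }
  return true;
}

// Moving-least-squares (locally weighted linear) interpolation of scattered
// values onto a regular grid. Weights are Wendland-like (1 - (d/r)^2)^2.
// Exact for fields linear in position; a node coinciding with a sample point
// (within 1e-9 * radius) takes the sample value. Nodes that never reach 3
// usable neighbours after `tries` radius doublings are flagged invalid.
// [[Rcpp::export]]
List mls_interp_cpp(NumericVector px, NumericVector py, NumericMatrix V,
                    NumericVector gx, NumericVector gy, double radius,
                    int tries) {
  const int n = px.size(), m = V.ncol();
  const int ngx = gx.size(), ngy = gy.size();
  const int nn = ngx * ngy;
  NumericMatrix out(nn, m);
  LogicalVector ok(nn);
  CellHash hash(px, py, radius);
  std::vector<int> cand;
  std::vector<int> use;
  std::vector<double> w;

  for (int jy = 0; jy < ngy; ++jy) {
    for (int jx = 0; jx < ngx; ++jx) {
      const int node = jy * ngx + jx;
      const double X = gx[jx], Y = gy[jy];
      double r = radius;
      bool done = false;
      for (int attempt = 0; attempt < tries && !done; ++attempt, r *= 2.0) {
        hash.gather(X, Y, r, cand);
        use.clear(); w.clear();
        const double r2 = r * r;
        int snap = -1;
        double snap_d2 = 1e-18 * radius * radius;
        for (size_t k = 0; k < cand.size(); ++k) {
          const int i = cand[k];
          const double dx = px[i] - X, dy = py[i] - Y;
          const double d2 = dx * dx + dy * dy;
          if (d2 <= r2) {
            if (d2 < snap_d2) { snap = i; break; }
            const double t = 1.0 - d2 / r2;
            use.push_back(i);
            w.push_back(t * t);
          }
        }
        if (snap >= 0) {
          for (int c = 0; c < m; ++c) out(node, c) = V(snap, c);
          ok[node] = true;
          done = true;
          break;
        }
        if ((int)use.size() < 3) continue;
        // weighted normal equations for [1, dx, dy]
        double A[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
        for (size_t k = 0; k < use.size(); ++k) {
          const int i = use[k];
          const double dx = px[i] - X, dy = py[i] - Y, wk = w[k];
          A[0][0] += wk;       A[0][1] += wk * dx;      A[0][2] += wk * dy;
          A[1][1] += wk * dx * dx; A[1][2] += wk * dx * dy;
          A[2][2] += wk * dy * dy;
        }
        A[1][0] = A[0][1]; A[2][0] = A[0][2]; A[2][1] = A[1][2];
        bool all_ok = true;
        for (int c = 0; c < m && all_ok; ++c) {
          double rhs[3] = {0, 0, 0};
          for (size_t k = 0; k < use.size(); ++k) {
            const int i = use[k];
            const double dx = px[i] - X, dy = py[i] - Y, wk = w[k];
            const double v = V(i, c);
            rhs[0] += wk * v; rhs[1] += wk * dx * v; rhs[2] += wk * dy * v;
          }
          double b[3];
          double Acopy[3][3];
          for (int ii = 0; ii < 3; ++ii)
            for (int jj = 0; jj < 3; ++jj) Acopy[ii][jj] = A[ii][jj];
          if (!solve3(Acopy, rhs, b)) { all_ok = false; break; }
          out(node, c) = b[0];
        }
        if (all_ok) { ok[node] = true; done = true; }
      }
      if (!done && !ok[node]) {
        for (int c = 0; c < m; ++c) out(node, c) = NA_REAL;
      }
    }
  }
  return List::create(_["values"] = out, _["ok"] = ok);
}

struct FieldView {
  const NumericVector& x;
  const NumericVector& y;
  const NumericMatrix& vx;
  const NumericMatrix& vy;
  const LogicalMatrix& mask;
  double x0, y0, hx, hy;
  int nx, ny;
  FieldView(const NumericVector& x_, const NumericVector& y_,
            const NumericMatrix& vx_, const NumericMatrix& vy_,
            const LogicalMatrix& mask_)
      : x(x_), y(y_), vx(vx_), vy(vy_), mask(mask_) {
    nx = x.size(); ny = y.size();
    x0 = x[0]; y0 = y[0];
    hx = (x[nx - 1] - x0) / (nx - 1);
    hy = (y[ny - 1] - y0) / (ny - 1);
  }
  // bilinear velocity; false when outside the grid or in a masked cell
  bool velocity(double X, double Y, double& u, double& v) const {
    double fx = (X - x0) / hx, fy = (Y - y0) / hy;
    int ix = (int)std::floor(fx), iy = (int)std::floor(fy);
    if (ix < 0 || iy < 0 || ix >= nx - 1 || iy >= ny - 1) {
      // allow evaluation exactly on the upper boundary
      if (X == x[nx - 1] && ix == nx - 1) ix = nx - 2;
      else if (ix < 0 || ix >= nx - 1) return false;
      if (Y == y[ny - 1] && iy == ny - 1) iy = ny - 2;
      else if (iy < 0 || iy >= ny - 1) return false;
    }
    if (!(mask(ix, iy) && mask(ix + 1, iy) && mask(ix, iy + 1) &&
          mask(ix + 1, iy + 1)))
      return false;
    double tx = fx - ix, ty = fy - iy;
    u = (1 - tx) * (1 - ty) * vx(ix, iy) + tx * (1 - ty) * vx(ix + 1, iy) +
        (1 - tx) * ty * vx(ix, iy + 1) + tx * ty * vx(ix + 1, iy + 1);
    v = (1 - tx) * (1 - ty) * vy(ix, iy) + tx * (1 - ty) * vy(ix + 1, iy) +
        (1 - tx) * ty * vy(ix, iy + 1) + tx * ty * vy(ix + 1, iy + 1);
    return true;
  }
  bool inside(double X, double Y) const {
    return X >= x0 && X <= x[nx - 1] && Y >= y0 && Y <= y[ny - 1];
  }
};

// Fixed-step midpoint (RK2) particle advection with bilinear lookup.
// status: 0 = exited grid / entered invalid cell, 1 = converged
// (displacement < tol), 2 = max_steps reached.
// [[Rcpp::export]]
List advect_cpp(NumericVector x, NumericVector y, NumericMatrix vx,
                NumericMatrix vy, LogicalMatrix mask, NumericVector sx,
                NumericVector sy, double h, int max_steps, double tol,
                bool record_paths) {
  FieldView F(x, y, vx, vy, mask);
  const int n = sx.size();
  NumericVector ex(n), ey(n);
  IntegerVector steps(n), status(n);
  List paths(record_paths ? n : 0);
  const double xmin = F.x0, xmax = x[x.size() - 1];
  const double ymin = F.y0, ymax = y[y.size() - 1];

  for (int i = 0; i < n; ++i) {
    double X = sx[i], Y = sy[i];
    std::vector<double> path_x, path_y;
    if (record_paths) { path_x.push_back(X); path_y.push_back(Y); }
    int st = 2, k = 0;
    for (; k < max_steps; ++k) {
      double u, v;
      if (!F.velocity(X, Y, u, v)) { st = 0; break; }
      double Xm = X + 0.5 * h * u, Ym = Y + 0.5 * h * v;
      double um, vm;
      if (!F.velocity(Xm, Ym, um, vm)) { um = u; vm = v; }  // Euler fallback
      double dX = h * um, dY = h * vm;
      double Xn = X + dX, Yn = Y + dY;
      if (!F.inside(Xn, Yn)) {
        // clip the final move to the grid boundary
        double t = 1.0;
        if (dX > 0) t = std::min(t, (xmax - X) / dX);
        if (dX < 0) t = std::min(t, (xmin - X) / dX);
        if (dY > 0) t = std::min(t, (ymax - Y) / dY);
        if (dY < 0) t = std::min(t, (ymin - Y) / dY);
        X += t * dX; Y += t * dY;
        if (record_paths) { path_x.push_back(X); path_y.push_back(Y); }
        st = 0; ++k;
        break;
      }
      X = Xn; Y = Yn;
      if (record_paths) { path_x.push_back(X); path_y.push_back(Y); }
      if (std::sqrt(dX * dX + dY * dY) < tol) { st = 1; ++k; break; }
    }
    ex[i] = X; ey[i] = Y; steps[i] = k; status[i] = st;
    if (record_paths) {
      NumericMatrix P(path_x.size(), 2);
      for (size_t j = 0; j < path_x.size(); ++j) {
        P(j, 0) = path_x[j]; P(j, 1) = path_y[j];
      }
      paths[i] = P;
    }
  }
  List out = List::create(_["end_x"] = ex, _["end_y"] = ey,
                          _["steps"] = steps, _["status"] = status);
  if (record_paths) out["paths"] = paths;
  return out;
}
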