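// Numerical kernels: trilinear interpolation, separable Gaussian smoothing,
// linear-elastic energy of a displacement grid, 26-connected component
// labelling, and the convolution/pooling primitives of the 3D U-Net.
// All voxel indices are 0-based; linear index = i + nx*(j + ny*k), matching
// the storage order of an R array.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline R_xlen_t lin3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
}

// Trilinear interpolation at continuous 0-based voxel coordinates.
// Outside voxels read as 0 ("zero background"); with clamp = true the
// coordinates are clamped to the grid instead (nearest-border extension,
// used for displacement-field extrapolation).
// [[Rcpp::export]]
List cpp_interp3(NumericVector vol, IntegerVector dim, NumericMatrix pts,
                 bool gradient, bool clamp) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector val(n);
  NumericMatrix grad(gradient ? n : 1, 3);
  const double* v = REAL(vol);

  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (clamp) {
      x = std::min(std::max(x, 0.0), (double)(nx - 1));
      y = std::min(std::max(y, 0.0), (double)(ny - 1));
      z = std::min(std::max(z, 0.0), (double)(nz - 1));
    }
    if (!R_finite(x) || !R_finite(y) || !R_finite(z) ||
        x <= -1.0 || y <= -1.0 || z <= -1.0 ||
        x >= (double)nx || y >= (double)ny || z >= (double)nz) {
      val[p] = 0.0;
      if (gradient) { grad(p,0)=0; grad(p,1)=0; grad(p,2)=0; }
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c[2][2][2];
    for (int di = 0; di < 2; ++di)
      for (int dj = 0; dj < 2; ++dj)
        for (int dk = 0; dk < 2; ++dk) {
          int i = i0 + di, j = j0 + dj, k = k0 + dk;
          c[di][dj][dk] = (i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz)
            ? v[lin3(i, j, k, nx, ny)] : 0.0;
        }
    double c00 = c[0][0][0]*(1-fx) + c[1][0][0]*fx;
    double c10 = c[0][1][0]*(1-fx) + c[1][1][0]*fx;
    double c01 = c[0][0][1]*(1-fx) + c[1][0][1]*fx;
    double c11 = c[0][1][1]*(1-fx) + c[1][1][1]*fx;
    double c0 = c00*(1-fy) + c10*fy;
    double c1 = c01*(1-fy) + c11*fy;
    val[p] = c0*(1-fz) + c1*fz;
    if (gradient) {
      double gx00 = c[1][0][0]-c[0][0][0], gx10 = c[1][1][0]-c[0][1][0];
      double gx01 = c[1][0][1]-c[0][0][1], gx11 = c[1][1][1]-c[0][1][1];
      grad(p,0) = ((gx00*(1-fy)+gx10*fy)*(1-fz) + (gx01*(1-fy)+gx11*fy)*fz);
      grad(p,1) = ((c10-c00)*(1-fz) + (c11-c01)*fz);
      grad(p,2) = (c1 - c0);
    }
  }
  if (gradient) return List::create(_["value"] = val, _["grad"] = grad);
  return List::create(_["value"] = val);
}

// Separable Gaussian smoothing, replicate (Neumann) borders, kernel
// truncated at 3 sigma and renormalized (mass-preserving in the interior).
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, IntegerVector dim, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (sigma <= 0) return clone(vol);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> w(2 * r + 1);
  double s = 0;
  for (int t = -r; t <= r; ++t) { w[t + r] = std::exp(-0.5 * t * t / (sigma * sigma)); s += w[t + r]; }
  for (auto& x : w) x /= s;

  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(REAL(vol), REAL(vol) + n), b(n);
  const int nd[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};

  for (int ax = 0; ax < 3; ++ax) {
    const int m = nd[ax];
    const R_xlen_t st = stride[ax];
    for (R_xlen_t base = 0; base < n; ++base) {
      // iterate only over line starts: coordinate along ax must be 0
      R_xlen_t coord = (base / st) % m;
      if (coord != 0) continue;
      for (int i = 0; i < m; ++i) {
        double acc = 0;
        for (int t = -r; t <= r; ++t) {
          int ii = std::min(std::max(i + t, 0), m - 1);
          acc += w[t + r] * a[base + (R_xlen_t)ii * st];
        }
        b[base + (R_xlen_t)i * st] = acc;
      }
    }
    std::swap(a, b);
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), REAL(out));
  out.attr("dim") = dim;
  return out;
}

// 3x3x3 neighbourhood sum (zero outside). Used as a local-density proxy
// when weighting landmark placement toward mask corners/edges.
// [[Rcpp::export]]
NumericVector cpp_boxsum3(NumericVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* v = REAL(vol);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
                acc += v[lin3(ii, jj, kk, nx, ny)];
            }
        out[lin3(i, j, k, nx, ny)] = acc;
      }
  out.attr("dim") = dim;
  return out;
}

// Discretized linear-elastic potential of a displacement grid u (mm) and its
// gradient. S(u) = sum_x h3 * [ mu/4 * sum_{j,k} (D_j u_k + D_k u_j)^2
//                              + lambda/2 * (div u)^2 ]
// with central differences in the interior and one-sided differences at the
// borders (Neumann handling). u is (#nodes x 3); grid has dims `dim` and
// physical node spacing `spacing` (mm).
// [[Rcpp::export]]
List cpp_elastic3(NumericMatrix u, IntegerVector dim, NumericVector spacing,
                  double mu, double lambda, bool want_grad) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double h3 = spacing[0] * spacing[1] * spacing[2];
  NumericMatrix grad(want_grad ? n : 1, 3);
  double energy = 0;

  const int nd[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};
  const double hh[3] = {spacing[0], spacing[1], spacing[2]};

  // stencil for D_a at coordinate c (along axis a): two (offset, weight) pairs
  auto stencil = [&](int a, int c, R_xlen_t* off, double* wt) {
    if (nd[a] == 1) { off[0] = 0; off[1] = 0; wt[0] = 0; wt[1] = 0; return; }
    if (c == 0)            { off[0] = stride[a]; off[1] = 0;          wt[0] =  1.0/hh[a]; wt[1] = -1.0/hh[a]; }
    else if (c == nd[a]-1) { off[0] = 0;         off[1] = -stride[a]; wt[0] =  1.0/hh[a]; wt[1] = -1.0/hh[a]; }
    else                   { off[0] = stride[a]; off[1] = -stride[a]; wt[0] = 0.5/hh[a];  wt[1] = -0.5/hh[a]; }
  };

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t x = lin3(i, j, k, nx, ny);
        const int cc[3] = {i, j, k};
        R_xlen_t off[3][2]; double wt[3][2];
        double D[3][3]; // D[a][b] = D_a u_b at x
        for (int a = 0; a < 3; ++a) {
          stencil(a, cc[a], off[a], wt[a]);
          for (int b = 0; b < 3; ++b)
            D[a][b] = wt[a][0] * u(x + off[a][0], b) + wt[a][1] * u(x + off[a][1], b);
        }
        double div = D[0][0] + D[1][1] + D[2][2];
        double e = 0;
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b) {
            double sab = D[a][b] + D[b][a];
            e += 0.25 * mu * sab * sab;
          }
        e += 0.5 * lambda * div * div;
        energy += h3 * e;

        if (want_grad) {
          for (int a = 0; a < 3; ++a)
            for (int b = 0; b < 3; ++b) {
              double sab = D[a][b] + D[b][a];
              // d/du of (mu/4) sab^2: coefficient mu/2 * sab on each D term
              double c1 = h3 * 0.5 * mu * sab;
              grad(x + off[a][0], b) += c1 * wt[a][0];
              grad(x + off[a][1], b) += c1 * wt[a][1];
              grad(x + off[b][0], a) += c1 * wt[b][0];
              grad(x + off[b][1], a) += c1 * wt[b][1];
            }
          double c2 = h3 * lambda * div;
          for (int a = 0; a < 3; ++a) {
            grad(x + off[a][0], a) += c2 * wt[a][0];
            grad(x + off[a][1], a) += c2 * wt[a][1];
          }
        }
      }
  if (want_grad) return List::create(_["value"] = energy, _["grad"] = grad);
  return List::create(_["value"] = energy);
}

// 26-connected component labelling of a binary grid (BFS flood fill).
// Returns integer labels, 0 = background, components numbered from 1.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  const int* m = LOGICAL(mask);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!m[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int k = cur / ((R_xlen_t)nx * ny);
      int rem = cur % ((R_xlen_t)nx * ny);
      int j = rem / nx, i = rem % nx;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
            R_xlen_t t = lin3(ii, jj, kk, nx, ny);
            if (m[t] && !lab[t]) { lab[t] = next; q.push(t); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---- 3D U-Net primitives -------------------------------------------------
// Activations are stored as (#voxels x #channels) matrices; spatial dims are
// passed alongside. Convolutions are 3x3x3, stride 1, zero padded ("same").

static arma::mat im2col3(const arma::mat& X, int nx, int ny, int nz) {
  const int cin = X.n_cols;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  arma::mat col(27 * cin, n);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t cidx = lin3(i, j, k, nx, ny);
        int r = 0;
        for (int c = 0; c < cin; ++c)
          for (int dk = -1; dk <= 1; ++dk)
            for (int dj = -1; dj <= 1; ++dj)
              for (int di = -1; di <= 1; ++di, ++r) {
                int ii = i + di, jj = j + dj, kk = k + dk;
                col(r, cidx) = (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
                  ? X(lin3(ii, jj, kk, nx, ny), c) : 0.0;
              }
      }
  return col;
}

static arma::mat col2im3(const arma::mat& dcol, int nx, int ny, int nz, int cin) {
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  arma::mat dX(n, cin, arma::fill::zeros);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t cidx = lin3(i, j, k, nx, ny);
        int r = 0;
        for (int c = 0; c < cin; ++c)
          for (int dk = -1; dk <= 1; ++dk)
            for (int dj = -1; dj <= 1; ++dj)
              for (int di = -1; di <= 1; ++di, ++r) {
                int ii = i + di, jj = j + dj, kk = k + dk;
                if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
                  dX(lin3(ii, jj, kk, nx, ny), c) += dcol(r, cidx);
              }
      }
  return dX;
}

// W is (cout x 27*cin), row-major over (channel, 27 offsets); b length cout.
// [[Rcpp::export]]
arma::mat cpp_conv3_fwd(const arma::mat& X, IntegerVector dim,
                        const arma::mat& W, const arma::vec& b) {
  arma::mat col = im2col3(X, dim[0], dim[1], dim[2]);
  arma::mat Y = (W * col).t();           // n x cout
  Y.each_row() += b.t();
  return Y;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(const arma::mat& X, IntegerVector dim,
                   const arma::mat& W, const arma::mat& dY) {
  arma::mat col = im2col3(X, dim[0], dim[1], dim[2]);
  arma::mat dYt = dY.t();                // cout x n
  arma::mat dW = dYt * col.t();
  arma::vec db = arma::sum(dYt, 1);
  arma::mat dcol = W.t() * dYt;
  arma::mat dX = col2im3(dcol, dim[0], dim[1], dim[2], X.n_cols);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// 2x2x2 max pooling, stride 2; dims must be even.
// [[Rcpp::export]]
List cpp_maxpool3_fwd(const arma::mat& X, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  const int C = X.n_cols;
  const R_xlen_t m = (R_xlen_t)mx * my * mz;
  arma::mat Y(m, C);
  arma::umat idx(m, C);
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i) {
        R_xlen_t o = lin3(i, j, k, mx, my);
        for (int c = 0; c < C; ++c) {
          double best = -1e300; R_xlen_t bi = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                R_xlen_t s = lin3(2*i + di, 2*j + dj, 2*k + dk, nx, ny);
                if (X(s, c) > best) { best = X(s, c); bi = s; }
              }
          Y(o, c) = best; idx(o, c) = bi;
        }
      }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool3_bwd(const arma::umat& idx, const arma::mat& dY, int n_in) {
  arma::mat dX(n_in, dY.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < dY.n_cols; ++c)
    for (arma::uword o = 0; o < dY.n_rows; ++o)
      dX(idx(o, c), c) += dY(o, c);
  return dX;
}
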