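// Compiled kernels for 3D patch CNNs and surface metrics.
//
// Volumes are passed as N x C matrices where N = nx*ny*nz voxels in R's
// column-major order (x fastest) and C is the channel count. Convolutions
// use "same" zero padding with odd kernel width k; the im2col feature
// index is f = c*k^3 + o (channel-major, offset o enumerated z,y,x-major
// to match the loop below), and weight matrices are (C_in*k^3) x C_out.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col3(const arma::mat& x, int nx, int ny, int nz, int k,
                    arma::mat& cols) {
  const int N = nx * ny * nz;
  const int k3 = k * k * k;
  const int r = k / 2;
  const int Cin = x.n_cols;
  cols.zeros(N, (arma::uword)Cin * k3);
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x.colptr(c);
    int o = 0;
    for (int dz = -r; dz <= r; ++dz) {
      for (int dy = -r; dy <= r; ++dy) {
        for (int dx = -r; dx <= r; ++dx, ++o) {
          double* col = cols.colptr((arma::uword)c * k3 + o);
          // destination voxel (ix,iy,iz) reads source (ix+dx, iy+dy, iz+dz)
          int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
          int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
          int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
          for (int iz = z0; iz < z1; ++iz) {
            for (int iy = y0; iy < y1; ++iy) {
              const double* src =
                  xc + (size_t)(iz + dz) * nx * ny + (size_t)(iy + dy) * nx;
              double* dst = col + (size_t)iz * nx * ny + (size_t)iy * nx;
              std::memcpy(dst + x0, src + x0 + dx,
                          (size_t)(x1 - x0) * sizeof(double));
            }
          }
        }
      }
    }
  }
  (void)N;
}

// [[Rcpp::export(name = ".conv3Forward")]]
arma::mat conv3Forward(const arma::mat& x, IntegerVector dims,
                       const arma::mat& W, const arma::vec& bias, int k) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  arma::mat out;
  if (k == 1) {
    out = x * W;
  } else {
    arma::mat cols;
    im2col3(x, nx, ny, nz, k, cols);
    out = cols * W;
  }
  out.each_row() += bias.t();
  return out;
}

// [[Rcpp::export(name = ".conv3Backward")]]
List conv3Backward(const arma::mat& x, IntegerVector dims, const arma::mat& W,
                   const arma::mat& gradOut, int k) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const int Cin = x.n_cols;
  arma::mat gW, gx;
  arma::vec gb = arma::sum(gradOut, 0).t();
  if (k == 1) {
    gW = x.t() * gradOut;
    gx = gradOut * W.t();
    return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
  }
  arma::mat cols;
  im2col3(x, nx, ny, nz, k, cols);
  gW = cols.t() * gradOut;
  arma::mat gcols = gradOut * W.t();  // N x Cin*k^3
  const int k3 = k * k * k;
  const int r = k / 2;
  gx.zeros(x.n_rows, Cin);
  // scatter-add: reverse of the im2col gather
  for (int c = 0; c < Cin; ++c) {
    double* gxc = gx.colptr(c);
    int o = 0;
    for (int dz = -r; dz <= r; ++dz) {
      for (int dy = -r; dy <= r; ++dy) {
        for (int dx = -r; dx <= r; ++dx, ++o) {
          const double* col = gcols.colptr((arma::uword)c * k3 + o);
          int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
          int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
          int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
          for (int iz = z0; iz < z1; ++iz) {
            for (int iy = y0; iy < y1; ++iy) {
              const double* src = col + (size_t)iz * nx * ny + (size_t)iy * nx;
              double* dst =
                  gxc + (size_t)(iz + dz) * nx * ny + (size_t)(iy + dy) * nx;
              for (int ix = x0; ix < x1; ++ix) dst[ix + dx] += src[ix];
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// Connected-component labeling on a binary mask, 6- or 26-connectivity.
// [[Rcpp::export(name = ".ccLabel")]]
IntegerVector ccLabel(LogicalVector mask, IntegerVector dims, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t N = (size_t)nx * ny * nz;
  IntegerVector lab(N, 0);
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }
  std::vector<size_t> stack;
  int cur = 0;
  for (size_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    stack.clear();
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      size_t v = stack.back();
      stack.pop_back();
      int iz = (int)(v / ((size_t)nx * ny));
      int rem = (int)(v % ((size_t)nx * ny));
      int iy = rem / nx, ix = rem % nx;
      for (size_t j = 0; j < ox.size(); ++j) {
        int jx = ix + ox[j], jy = iy + oy[j], jz = iz + oz[j];
        if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
          continue;
        size_t w = (size_t)jz * nx * ny + (size_t)jy * nx + jx;
        if (mask[w] && lab[w] == 0) {
          lab[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}

// For each row of A (physical coordinates), the Euclidean distance to the
// nearest row of B. Brute force; surfaces at phantom scale stay small.
// [[Rcpp::export(name = ".nearestDistances")]]
NumericVector nearestDistances(const arma::mat& A, const arma::mat& B) {
  const arma::uword nA = A.n_rows, nB = B.n_rows;
  NumericVector out(nA);
  for (arma::uword i = 0; i < nA; ++i) {
    double best = R_PosInf;
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (arma::uword j = 0; j < nB; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
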