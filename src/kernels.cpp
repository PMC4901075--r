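#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>

using namespace Rcpp;

// Separable Gaussian convolution along one axis of a 3-D lattice stored
// column-major (x fastest). Edge taps are renormalised so that a constant
// field is left unchanged (normalised convolution).
static void conv_axis(std::vector<double> &v, std::vector<double> &buf,
                      int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0.0) return;
  int half = (int)std::ceil(4.0 * sigma);
  std::vector<double> w(2 * half + 1);
  for (int i = -half; i <= half; ++i)
    w[i + half] = std::exp(-0.5 * (double)i * i / (sigma * sigma));

  int n[3] = {nx, ny, nz};
  int stride[3] = {1, nx, nx * ny};
  int len = n[axis], st = stride[axis];
  int na = n[(axis + 1) % 3], nb = n[(axis + 2) % 3];
  int sa = stride[(axis + 1) % 3], sb = stride[(axis + 2) % 3];

  // normalisers for edge taps (renormalised convolution)
  double wtot = 0.0;
  for (int i = 0; i < 2 * half + 1; ++i) wtot += w[i];
  std::vector<double> line(len);
  for (int b = 0; b < nb; ++b) {
    for (int a = 0; a < na; ++a) {
      int base = a * sa + b * sb;
      for (int i = 0; i < len; ++i) line[i] = v[base + i * st];
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        int lo = std::max(0, i - half), hi = std::min(len - 1, i + half);
        if (lo == i - half && hi == i + half) {
          const double *lp = &line[i - half];
          for (int j = 0; j <= 2 * half; ++j) acc += w[j] * lp[j];
          buf[i] = acc / wtot;
        } else {
          double wsum = 0.0;
          for (int j = lo; j <= hi; ++j) {
            double wt = w[j - i + half];
            acc += wt * line[j];
            wsum += wt;
          }
          buf[i] = acc / wsum;
        }
      }
      for (int i = 0; i < len; ++i) v[base + i * st] = buf[i];
    }
  }
}

static void smooth3(std::vector<double> &v, int nx, int ny, int nz,
                    double sx, double sy, double sz) {
  std::vector<double> buf(std::max(nx, std::max(ny, nz)));
  conv_axis(v, buf, nx, ny, nz, 0, sx);
  conv_axis(v, buf, nx, ny, nz, 1, sy);
  conv_axis(v, buf, nx, ny, nz, 2, sz);
}

// [[Rcpp::export(name = ".cpp_smooth3d")]]
NumericVector cpp_smooth3d(NumericVector vol, IntegerVector dims,
                           NumericVector sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> v(vol.begin(), vol.end());
  smooth3(v, nx, ny, nz, sigma_vox[0], sigma_vox[1], sigma_vox[2]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dims;
  return out;
}

// Neighbour offsets for 6/18/26 connectivity.
static std::vector<std::array<int, 3>> neighbours(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

// Connected-component labelling by breadth-first search.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> off = neighbours(connectivity);
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
      for (size_t k = 0; k < off.size(); ++k) {
        int x = cx + off[k][0], y = cy + off[k][1], z = cz + off[k][2];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        int idx = x + nx * (y + ny * z);
        if (mask[idx] && lab[idx] == 0) {
          lab[idx] = next;
          stack.push_back(idx);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Monte-Carlo null distribution of the maximal suprathreshold cluster size:
// per iteration fill the grid with unit Gaussian noise, smooth, restandardise
// within the mask, threshold one-sided at zcut, record the largest
// 'connectivity'-connected cluster among masked voxels. Uses R's RNG so the
// caller's set.seed() governs reproducibility.
// Returns an n_iter x 2 matrix: max cluster size, suprathreshold count.
// [[Rcpp::export(name = ".cpp_mc_max_cluster")]]
IntegerMatrix cpp_mc_max_cluster(IntegerVector dims, NumericVector sigma_vox,
                                 LogicalVector mask, double zcut, int n_iter,
                                 int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<int> midx;
  for (int i = 0; i < n; ++i)
    if (mask[i]) midx.push_back(i);
  int nm = (int)midx.size();
  std::vector<double> v(n);
  std::vector<int> lab(n), csize;
  std::vector<int> stack;
  std::vector<std::array<int, 3>> off = neighbours(connectivity);
  IntegerMatrix out(n_iter, 2);

  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < n; ++i) v[i] = norm_rand();
    smooth3(v, nx, ny, nz, sigma_vox[0], sigma_vox[1], sigma_vox[2]);
    double s1 = 0.0, s2 = 0.0;
    for (int k = 0; k < nm; ++k) {
      double x = v[midx[k]];
      s1 += x;
      s2 += x * x;
    }
    double mu = s1 / nm;
    double sd = std::sqrt((s2 - nm * mu * mu) / (nm - 1));
    double cut = mu + zcut * sd;  // equivalent to standardising then zcut

    std::fill(lab.begin(), lab.end(), 0);
    int best = 0, next = 0, n_supra = 0;
    for (int k = 0; k < nm; ++k)
      if (v[midx[k]] >= cut) ++n_supra;
    for (int k = 0; k < nm; ++k) {
      int s = midx[k];
      if (v[s] < cut || lab[s] != 0) continue;
      ++next;
      int sz = 0;
      lab[s] = next;
      stack.push_back(s);
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        ++sz;
        int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
        for (size_t q = 0; q < off.size(); ++q) {
          int x = cx + off[q][0], y = cy + off[q][1], z = cz + off[q][2];
          if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
            continue;
          int idx = x + nx * (y + ny * z);
          if (mask[idx] && v[idx] >= cut && lab[idx] == 0) {
            lab[idx] = next;
            stack.push_back(idx);
          }
        }
      }
      if (sz > best) best = sz;
    }
    out(it, 0) = best;
    out(it, 1) = n_supra;
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// l2 norm of the edge-renormalised kernel at every position along one axis;
// for separable smoothing of iid noise, the per-voxel variance factorises
// into the product of these per-axis norms.
static std::vector<double> axis_var(int len, double s) {
  std::vector<double> out(len, 1.0);
  if (s <= 0.0) return out;
  int half = (int)std::ceil(4.0 * s);
  std::vector<double> w(2 * half + 1);
  for (int i = -half; i <= half; ++i)
    w[i + half] = std::exp(-0.5 * (double)i * i / (s * s));
  for (int i = 0; i < len; ++i) {
    double wsum = 0.0, w2 = 0.0;
    int lo = std::max(0, i - half), hi = std::min(len - 1, i + half);
    for (int j = lo; j <= hi; ++j) {
      double wt = w[j - i + half];
      wsum += wt;
      w2 += wt * wt;
    }
    out[i] = w2 / (wsum * wsum);
  }
  return out;
}

// Spatially smoothed, temporally AR(1) Gaussian noise for one run.
// Returns an n_vox x n_scan matrix. Each innovation field is smoothed and
// restandardised per voxel with the exact separable kernel norms, so every
// voxel's marginal SD is `sigma` (the AR innovation carries sqrt(1-rho^2)).
// [[Rcpp::export(name = ".cpp_noise_run")]]
NumericMatrix cpp_noise_run(IntegerVector dims, NumericVector sigma_vox,
                            double sigma, double rho, int n_scan) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<double> vx = axis_var(nx, sigma_vox[0]);
  std::vector<double> vy = axis_var(ny, sigma_vox[1]);
  std::vector<double> vz = axis_var(nz, sigma_vox[2]);
  std::vector<double> renorm(n);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        renorm[i + nx * (j + ny * k)] =
          1.0 / std::sqrt(vx[i] * vy[j] * vz[k]);
  double innov_sd = std::sqrt(1.0 - rho * rho);

  NumericMatrix out(n, n_scan);
  std::vector<double> v(n), state(n, 0.0);
  for (int t = 0; t < n_scan; ++t) {
    for (int i = 0; i < n; ++i) v[i] = norm_rand();
    smooth3(v, nx, ny, nz, sigma_vox[0], sigma_vox[1], sigma_vox[2]);
    if (t == 0) {
      for (int i = 0; i < n; ++i) state[i] = v[i] * renorm[i];
    } else {
      for (int i = 0; i < n; ++i)
        state[i] = rho * state[i] + innov_sd * renorm[i] * v[i];
    }
    for (int i = 0; i < n; ++i) out(i, t) = sigma * state[i];
  }
  return out;
}
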