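// Rotation-based parallel-beam projector for emission tomography.
//
// The system operator per view is a composition of four factors, each of
// which is self-adjoint or implemented together with its exact transpose:
//   1. in-plane bilinear rotation about the z (scanner) axis,
//   2. diagonal attenuation weighting exp(-integral of mu to the detector),
//   3. depth-dependent separable Gaussian blur (collimator-detector
//      response), symmetric kernel + zero padding => self-adjoint,
//   4. summation along the detector normal (+y), adjoint = broadcast.
// cpp_backproject is therefore the exact matrix transpose of cpp_project,
// which OSEM requires.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Precomputed bilinear-rotation weights for one in-plane pixel map.
// Plane-contiguous application keeps the working set (one x-y plane) in
// cache while looping over z.
struct RotMap {
  std::vector<int> src;     // 4 source indices per output pixel (-1 = none)
  std::vector<double> w;    // matching weights
};

static RotMap make_rotmap(int nx, int ny, double ca, double sa) {
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  RotMap m;
  m.src.assign((size_t)nx * ny * 4, -1);
  m.w.assign((size_t)nx * ny * 4, 0.0);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      const double dx = i - cx, dy = j - cy;
      const double xs = cx + dx * ca + dy * sa;
      const double ys = cy - dx * sa + dy * ca;
      const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      const double fx = xs - x0, fy = ys - y0;
      const int xi[2] = {x0, x0 + 1}, yi[2] = {y0, y0 + 1};
      const double wx[2] = {1.0 - fx, fx}, wy[2] = {1.0 - fy, fy};
      const size_t base = ((size_t)i + (size_t)nx * j) * 4;
      int t = 0;
      for (int b = 0; b < 2; ++b) {
        for (int a = 0; a < 2; ++a, ++t) {
          if (yi[b] < 0 || yi[b] >= ny || xi[a] < 0 || xi[a] >= nx) continue;
          const double w = wx[a] * wy[b];
          if (w == 0.0) continue;
          m.src[base + t] = xi[a] + nx * yi[b];
          m.w[base + t] = w;
        }
      }
    }
  }
  return m;
}

// adjoint=false: gather (out(p) = in(R^{-1}p));
// adjoint=true: scatter with identical weights (exact transpose).
static void rotate_z(const double* in, double* out, int nx, int ny, int nz,
                     double ca, double sa, bool adjoint) {
  const RotMap m = make_rotmap(nx, ny, ca, sa);
  const size_t pl = (size_t)nx * ny;
  for (int k = 0; k < nz; ++k) {
    const double* ip = in + pl * k;
    double* op = out + pl * k;
    for (size_t p = 0; p < pl; ++p) {
      const size_t base = p * 4;
      if (!adjoint) {
        double acc = op[p];
        for (int t = 0; t < 4; ++t) {
          const int s = m.src[base + t];
          if (s >= 0) acc += m.w[base + t] * ip[s];
        }
        op[p] = acc;
      } else {
        const double v = ip[p];
        if (v == 0.0) continue;
        for (int t = 0; t < 4; ++t) {
          const int s = m.src[base + t];
          if (s >= 0) op[s] += m.w[base + t] * v;
        }
      }
    }
  }
}

// Attenuation survival factor toward a detector at +y:
// att(x,y,z) = exp(-vox * (mu(x,y,z)/2 + sum_{y' > y} mu(x,y',z))).
static void atten_factor(const double* mur, double* att, int nx, int ny, int nz,
                         double vox) {
  const size_t pl = (size_t)nx * ny;
  std::vector<double> cum(nx);
  for (int k = 0; k < nz; ++k) {
    std::fill(cum.begin(), cum.end(), 0.0);
    for (int j = ny - 1; j >= 0; --j) {
      const size_t row = (size_t)nx * j + pl * k;
      for (int i = 0; i < nx; ++i) {
        att[row + i] = std::exp(-vox * (cum[i] + 0.5 * mur[row + i]));
        cum[i] += mur[row + i];
      }
    }
  }
}

static std::vector<double> gauss_kernel(double sigma_pix) {
  if (sigma_pix < 1e-8) return std::vector<double>(1, 1.0);
  int r = (int)std::ceil(3.0 * sigma_pix);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * t * t / (sigma_pix * sigma_pix));
    s += k[t + r];
  }
  for (double& v : k) v /= s;
  return k;
}

// Symmetric separable blur of the (x,z) plane at depth index iy, in place.
// Zero padding keeps the operator symmetric (self-adjoint).
static void blur_plane(double* vol, int nx, int ny, int nz, int iy,
                       const std::vector<double>& ker) {
  const int r = ((int)ker.size() - 1) / 2;
  if (r == 0) return;
  const size_t pl = (size_t)nx * ny;
  std::vector<double> buf((size_t)nx * nz), tmp((size_t)nx * nz);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i)
      buf[(size_t)i + (size_t)nx * k] = vol[(size_t)i + (size_t)nx * iy + pl * k];
  // along x
  for (int k = 0; k < nz; ++k) {
    for (int i = 0; i < nx; ++i) {
      double acc = 0.0;
      const int lo = std::max(0, i - r), hi = std::min(nx - 1, i + r);
      for (int t = lo; t <= hi; ++t)
        acc += ker[t - i + r] * buf[(size_t)t + (size_t)nx * k];
      tmp[(size_t)i + (size_t)nx * k] = acc;
    }
  }
  // along z
  for (int i = 0; i < nx; ++i) {
    for (int k = 0; k < nz; ++k) {
      double acc = 0.0;
      const int lo = std::max(0, k - r), hi = std::min(nz - 1, k + r);
      for (int t = lo; t <= hi; ++t)
        acc += ker[k - t + r] * tmp[(size_t)i + (size_t)nx * t];
      buf[(size_t)i + (size_t)nx * k] = acc;
    }
  }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i)
      vol[(size_t)i + (size_t)nx * iy + pl * k] = buf[(size_t)i + (size_t)nx * k];
}

// depth (cm) of plane iy from the detector, which sits at orbit radius on +y
static inline double plane_depth(int iy, int ny, double vox, double orbit) {
  const double y_cm = (iy - 0.5 * (ny - 1)) * vox;
  return orbit - y_cm;
}

// [[Rcpp::export]]
NumericVector cpp_project(NumericVector act, NumericVector mu,
                          IntegerVector dim, NumericVector angles, double vox,
                          bool use_att, bool use_cdr, double sigma0,
                          double slope, double orbit) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], nv = angles.size();
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector views((size_t)nx * nz * nv);
  std::vector<double> ar(nvox), mr(nvox), att(nvox);
  for (int a = 0; a < nv; ++a) {
    const double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    std::fill(ar.begin(), ar.end(), 0.0);
    rotate_z(REAL(act), ar.data(), nx, ny, nz, ca, sa, false);
    if (use_att) {
      std::fill(mr.begin(), mr.end(), 0.0);
      rotate_z(REAL(mu), mr.data(), nx, ny, nz, ca, sa, false);
      atten_factor(mr.data(), att.data(), nx, ny, nz, vox);
      for (size_t t = 0; t < nvox; ++t) ar[t] *= att[t];
    }
    if (use_cdr) {
      for (int j = 0; j < ny; ++j) {
        double sg = sigma0 + slope * plane_depth(j, ny, vox, orbit);
        if (sg < 0) sg = 0;
        blur_plane(ar.data(), nx, ny, nz, j, gauss_kernel(sg / vox));
      }
    }
    const size_t pl = (size_t)nx * ny;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          views[(size_t)i + (size_t)nx * k + (size_t)nx * nz * a] +=
              vox * ar[(size_t)i + (size_t)nx * j + pl * k];
  }
  views.attr("dim") = IntegerVector::create(nx, nz, nv);
  return views;
}

// Full OSEM loop with per-view rotation maps and attenuation factors
// cached across iterations (they are fixed by mu and the geometry).
// subsetOrder: 1-based subset ids in update order; subset s owns 0-based
// views (s-1), (s-1)+nSubsets, ... Multiple independent measurement sets
// (y holding nRhs stacked sinogram sets) are reconstructed in one call,
// sharing the cached system model and sensitivity images.
// [[Rcpp::export]]
Rcpp::List cpp_osem(NumericVector y, NumericVector mu, IntegerVector dim,
                    NumericVector angles, double vox, bool use_att,
                    bool use_cdr, double sigma0, double slope, double orbit,
                    int nSubsets, int nIters, IntegerVector subsetOrder,
                    bool trackLoglik, int nRhs) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], nv = angles.size();
  const size_t nvox = (size_t)nx * ny * nz, npix = (size_t)nx * nz;
  const size_t pl = (size_t)nx * ny;

  std::vector<RotMap> maps; maps.reserve(nv);
  for (int a = 0; a < nv; ++a)
    maps.push_back(make_rotmap(nx, ny, std::cos(angles[a]),
                               std::sin(angles[a])));
  std::vector<std::vector<double>> att;
  if (use_att) {
    att.assign(nv, std::vector<double>());
    std::vector<double> mr(nvox);
    for (int a = 0; a < nv; ++a) {
      std::fill(mr.begin(), mr.end(), 0.0);
      const RotMap& m = maps[a];
      for (int k = 0; k < nz; ++k) {
        const double* ip = REAL(mu) + pl * k;
        double* op = mr.data() + pl * k;
        for (size_t p = 0; p < pl; ++p) {
          const size_t base = p * 4;
          double acc = 0.0;
          for (int t = 0; t < 4; ++t) {
            const int s = m.src[base + t];
            if (s >= 0) acc += m.w[base + t] * ip[s];
          }
          op[p] = acc;
        }
      }
      att[a].resize(nvox);
      atten_factor(mr.data(), att[a].data(), nx, ny, nz, vox);
    }
  }
  std::vector<std::vector<double>> kern(ny);
  if (use_cdr)
    for (int j = 0; j < ny; ++j) {
      double sg = sigma0 + slope * plane_depth(j, ny, vox, orbit);
      if (sg < 0) sg = 0;
      kern[j] = gauss_kernel(sg / vox);
    }

  std::vector<double> tmp(nvox);
  auto fpView = [&](const double* x, int a, double* view) {
    std::fill(tmp.begin(), tmp.end(), 0.0);
    const RotMap& m = maps[a];
    for (int k = 0; k < nz; ++k) {
      const double* ip = x + pl * k;
      double* op = tmp.data() + pl * k;
      for (size_t p = 0; p < pl; ++p) {
        const size_t base = p * 4;
        double acc = 0.0;
        for (int t = 0; t < 4; ++t) {
          const int s = m.src[base + t];
          if (s >= 0) acc += m.w[base + t] * ip[s];
        }
        op[p] = acc;
      }
    }
    if (use_att) {
      const double* av = att[a].data();
      for (size_t t = 0; t < nvox; ++t) tmp[t] *= av[t];
    }
    if (use_cdr)
      for (int j = 0; j < ny; ++j) blur_plane(tmp.data(), nx, ny, nz, j, kern[j]);
    std::fill(view, view + npix, 0.0);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const double* row = tmp.data() + (size_t)nx * j + pl * k;
        double* vr = view + (size_t)nx * k;
        for (int i = 0; i < nx; ++i) vr[i] += vox * row[i];
      }
  };
  auto bpView = [&](const double* view, int a, double* accum) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const double* vr = view + (size_t)nx * k;
        double* row = tmp.data() + (size_t)nx * j + pl * k;
        for (int i = 0; i < nx; ++i) row[i] = vox * vr[i];
      }
    if (use_cdr)
      for (int j = 0; j < ny; ++j) blur_plane(tmp.data(), nx, ny, nz, j, kern[j]);
    if (use_att) {
      const double* av = att[a].data();
      for (size_t t = 0; t < nvox; ++t) tmp[t] *= av[t];
    }
    const RotMap& m = maps[a];
    for (int k = 0; k < nz; ++k) {
      const double* ip = tmp.data() + pl * k;
      double* op = accum + pl * k;
      for (size_t p = 0; p < pl; ++p) {
        const double v = ip[p];
        if (v == 0.0) continue;
        const size_t base = p * 4;
        for (int t = 0; t < 4; ++t) {
          const int s = m.src[base + t];
          if (s >= 0) op[s] += m.w[base + t] * v;
        }
      }
    }
  };

  std::vector<std::vector<int>> subViews(nSubsets);
  for (int s = 0; s < nSubsets; ++s)
    for (int a = s; a < nv; a += nSubsets) subViews[s].push_back(a);

  std::vector<std::vector<double>> sens(nSubsets);
  std::vector<double> ones(npix, 1.0);
  for (int s = 0; s < nSubsets; ++s) {
    sens[s].assign(nvox, 0.0);
    for (int a : subViews[s]) bpView(ones.data(), a, sens[s].data());
  }

  const double eps = 1e-12;
  std::vector<double> view(npix), ratio(npix), upd(nvox);
  Rcpp::List xs(nRhs);
  NumericVector loglik(trackLoglik ? nIters * nRhs : 0);
  for (int r = 0; r < nRhs; ++r) {
    NumericVector x(nvox);
    std::fill(x.begin(), x.end(), 1.0);
    const double* yr = REAL(y) + npix * (size_t)nv * r;
    for (int it = 0; it < nIters; ++it) {
      for (int so = 0; so < subsetOrder.size(); ++so) {
        const int s = subsetOrder[so] - 1;
        std::fill(upd.begin(), upd.end(), 0.0);
        for (int a : subViews[s]) {
          fpView(REAL(x), a, view.data());
          const double* yv = yr + npix * a;
          for (size_t p = 0; p < npix; ++p)
            ratio[p] = yv[p] / std::max(view[p], eps);
          bpView(ratio.data(), a, upd.data());
        }
        for (size_t t = 0; t < nvox; ++t) {
          if (sens[s][t] > eps) x[t] *= upd[t] / sens[s][t];
          else x[t] = 0.0;
        }
      }
      if (trackLoglik) {
        double ll = 0.0;
        for (int a = 0; a < nv; ++a) {
          fpView(REAL(x), a, view.data());
          const double* yv = yr + npix * a;
          for (size_t p = 0; p < npix; ++p)
            ll += yv[p] * std::log(std::max(view[p], eps)) - view[p];
        }
        loglik[it + nIters * r] = ll;
      }
    }
    x.attr("dim") = dim;
    xs[r] = x;
  }
  return Rcpp::List::create(Rcpp::Named("x") = xs[0],
                            Rcpp::Named("xs") = xs,
                            Rcpp::Named("loglik") = loglik);
}

// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector views, NumericVector mu,
                              IntegerVector dim, NumericVector angles,
                              double vox, bool use_att, bool use_cdr,
                              double sigma0, double slope, double orbit) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], nv = angles.size();
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(nvox);
  std::vector<double> w(nvox), mr(nvox), att(nvox);
  const size_t pl = (size_t)nx * ny;
  for (int a = 0; a < nv; ++a) {
    const double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    // adjoint of summation: broadcast the view along y (times vox)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          w[(size_t)i + (size_t)nx * j + pl * k] =
              vox * views[(size_t)i + (size_t)nx * k + (size_t)nx * nz * a];
    if (use_cdr) {
      for (int j = 0; j < ny; ++j) {
        double sg = sigma0 + slope * plane_depth(j, ny, vox, orbit);
        if (sg < 0) sg = 0;
        blur_plane(w.data(), nx, ny, nz, j, gauss_kernel(sg / vox));
      }
    }
    if (use_att) {
      std::fill(mr.begin(), mr.end(), 0.0);
      rotate_z(REAL(mu), mr.data(), nx, ny, nz, ca, sa, false);
      atten_factor(mr.data(), att.data(), nx, ny, nz, vox);
      for (size_t t = 0; t < nvox; ++t) w[t] *= att[t];
    }
    rotate_z(w.data(), REAL(out), nx, ny, nz, ca, sa, true);
  }
  out.attr("dim") = dim;
  return out;
}
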