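// Numerical kernels: analytic GMM image rendering with gradients,
// density-map line-integral projection, map simulation from a GMM, and
// the Jacobian of internal-coordinate hydrogen placement.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double SQRT2PI = 2.5066282746310002;

// Render the analytic 2D projection of a 3D isotropic GMM.
// centers are in the map frame relative to the box center (Angstrom);
// rot (3x3) maps model coordinates into the projection frame, the view
// axis being the rotated z. Pixel i (0-based) sits at (i - npix/2) * pix.
// [[Rcpp::export]]
NumericMatrix cpp_render_gmm(NumericMatrix centers, NumericVector amps,
                             double width, NumericMatrix rot,
                             int npix, double pix) {
  int n = centers.nrow();
  NumericMatrix img(npix, npix);
  double s2 = 2.0 * width * width;
  double rad = 4.0 * width;
  int c0 = npix / 2;
  for (int a = 0; a < n; ++a) {
    double x = centers(a, 0), y = centers(a, 1), z = centers(a, 2);
    double u = rot(0, 0) * x + rot(0, 1) * y + rot(0, 2) * z;
    double v = rot(1, 0) * x + rot(1, 1) * y + rot(1, 2) * z;
    double ca = amps[a] * width * SQRT2PI;
    int i0 = std::max(0, (int)std::floor((u - rad) / pix) + c0);
    int i1 = std::min(npix - 1, (int)std::ceil((u + rad) / pix) + c0);
    int j0 = std::max(0, (int)std::floor((v - rad) / pix) + c0);
    int j1 = std::min(npix - 1, (int)std::ceil((v + rad) / pix) + c0);
    for (int j = j0; j <= j1; ++j) {
      double dv = (j - c0) * pix - v;
      for (int i = i0; i <= i1; ++i) {
        double du = (i - c0) * pix - u;
        img(i, j) += ca * std::exp(-(du * du + dv * dv) / s2);
      }
    }
  }
  return img;
}

// Backward pass of cpp_render_gmm: given dL/dimage, accumulate gradients
// with respect to the projected (rotated-frame) centers, amplitudes and the
// shared width. dcenters is in the projection frame (z component zero);
// the caller rotates it back with t(rot).
// [[Rcpp::export]]
List cpp_render_gmm_grad(NumericMatrix centers, NumericVector amps,
                         double width, NumericMatrix rot,
                         int npix, double pix, NumericMatrix dldi) {
  int n = centers.nrow();
  NumericMatrix dc(n, 3);
  NumericVector da(n);
  double dw = 0.0;
  double s2 = 2.0 * width * width;
  double w2 = width * width;
  double rad = 4.0 * width;
  int c0 = npix / 2;
  for (int a = 0; a < n; ++a) {
    double x = centers(a, 0), y = centers(a, 1), z = centers(a, 2);
    double u = rot(0, 0) * x + rot(0, 1) * y + rot(0, 2) * z;
    double v = rot(1, 0) * x + rot(1, 1) * y + rot(1, 2) * z;
    double ca = amps[a] * width * SQRT2PI;
    int i0 = std::max(0, (int)std::floor((u - rad) / pix) + c0);
    int i1 = std::min(npix - 1, (int)std::ceil((u + rad) / pix) + c0);
    int j0 = std::max(0, (int)std::floor((v - rad) / pix) + c0);
    int j1 = std::min(npix - 1, (int)std::ceil((v + rad) / pix) + c0);
    double gu = 0, gv = 0, ga = 0, gw = 0;
    for (int j = j0; j <= j1; ++j) {
      double dv = (j - c0) * pix - v;
      for (int i = i0; i <= i1; ++i) {
        double du = (i - c0) * pix - u;
        double r2 = du * du + dv * dv;
        double e = std::exp(-r2 / s2);
        double g = dldi(i, j) * ca * e;
        gu += g * du / w2;           // dI/du = ca*e*(du)/w2
        gv += g * dv / w2;
        ga += dldi(i, j) * e * width * SQRT2PI;
        gw += g * (1.0 / width + r2 / (w2 * width));
      }
    }
    dc(a, 0) = gu; dc(a, 1) = gv;
    da[a] = ga;
    dw += gw;
  }
  return List::create(_["dcenters"] = dc, _["damps"] = da, _["dwidth"] = dw);
}

static inline double trilinear(const NumericVector &vol, int nx, int ny,
                               int nz, double x, double y, double z) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
      z1 = std::min(z0 + 1, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double v000 = vol[x0 + nx * (y0 + ny * z0)], v100 = vol[x1 + nx * (y0 + ny * z0)];
  double v010 = vol[x0 + nx * (y1 + ny * z0)], v110 = vol[x1 + nx * (y1 + ny * z0)];
  double v001 = vol[x0 + nx * (y0 + ny * z1)], v101 = vol[x1 + nx * (y0 + ny * z1)];
  double v011 = vol[x0 + nx * (y1 + ny * z1)], v111 = vol[x1 + nx * (y1 + ny * z1)];
  double v00 = v000 + fx * (v100 - v000), v10 = v010 + fx * (v110 - v010);
  double v01 = v001 + fx * (v101 - v001), v11 = v011 + fx * (v111 - v011);
  double v0 = v00 + fy * (v10 - v00), v1 = v01 + fy * (v11 - v01);
  return v0 + fz * (v1 - v0);
}

// Line-integral projection of a cubic density grid along the rotated z
// axis. The grid is an nx*ny*nz array (x fastest); sample point for image
// pixel (i, j) at depth step t is t(rot) %*% (u, v, w) about the box
// center. Integration step equals the voxel size.
// [[Rcpp::export]]
NumericMatrix cpp_project_map(NumericVector vol, IntegerVector dims,
                              double voxel, NumericMatrix rot,
                              int npix, double pix) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix img(npix, npix);
  int c0 = npix / 2;
  double cx = nx / 2, cy = ny / 2, cz = nz / 2;
  double half = 0.5 * voxel * std::sqrt((double)(nx * nx + ny * ny + nz * nz));
  int nst = (int)std::ceil(2.0 * half / voxel);
  for (int j = 0; j < npix; ++j) {
    double v = (j - c0) * pix;
    for (int i = 0; i < npix; ++i) {
      double u = (i - c0) * pix;
      double acc = 0.0;
      for (int t = 0; t <= nst; ++t) {
        double w = -half + t * voxel;
        // model-frame point = t(rot) %*% c(u, v, w)
        double px = rot(0, 0) * u + rot(1, 0) * v + rot(2, 0) * w;
        double py = rot(0, 1) * u + rot(1, 1) * v + rot(2, 1) * w;
        double pz = rot(0, 2) * u + rot(1, 2) * v + rot(2, 2) * w;
        acc += trilinear(vol, nx, ny, nz, px / voxel + cx, py / voxel + cy,
                         pz / voxel + cz);
      }
      img(i, j) = acc * voxel;
    }
  }
  return img;
}

// Accumulate a GMM into a cubic 3D grid (box center at origin).
// [[Rcpp::export]]
NumericVector cpp_simulate_map(NumericMatrix centers, NumericVector amps,
                               double width, int n, double voxel) {
  NumericVector vol(n * n * n);
  double s2 = 2.0 * width * width;
  double rad = 4.0 * width;
  double c0 = n / 2;
  for (int a = 0; a < centers.nrow(); ++a) {
    double x = centers(a, 0) / voxel + c0;
    double y = centers(a, 1) / voxel + c0;
    double z = centers(a, 2) / voxel + c0;
    int r = (int)std::ceil(rad / voxel);
    int x0 = std::max(0, (int)x - r), x1 = std::min(n - 1, (int)x + r + 1);
    int y0 = std::max(0, (int)y - r), y1 = std::min(n - 1, (int)y + r + 1);
    int z0 = std::max(0, (int)z - r), z1 = std::min(n - 1, (int)z + r + 1);
    for (int k = z0; k <= z1; ++k)
      for (int j = y0; j <= y1; ++j)
        for (int i = x0; i <= x1; ++i) {
          double dx = (i - x) * voxel, dy = (j - y) * voxel, dz = (k - z) * voxel;
          vol[i + n * (j + n * k)] +=
            amps[a] * std::exp(-(dx * dx + dy * dy + dz * dz) / s2);
        }
  }
  return vol;
}

static inline void nerf_one(const double *a, const double *b, const double *c,
                            double dist, double ang, double tor, double *out) {
  double bc[3], ab[3], nrm[3], m[3];
  double nb = 0, na = 0;
  for (int k = 0; k < 3; ++k) { bc[k] = c[k] - b[k]; ab[k] = b[k] - a[k]; }
  nb = std::sqrt(bc[0]*bc[0] + bc[1]*bc[1] + bc[2]*bc[2]);
  for (int k = 0; k < 3; ++k) bc[k] /= (nb > 1e-12 ? nb : 1e-12);
  na = std::sqrt(ab[0]*ab[0] + ab[1]*ab[1] + ab[2]*ab[2]);
  for (int k = 0; k < 3; ++k) ab[k] /= (na > 1e-12 ? na : 1e-12);
  nrm[0] = ab[1]*bc[2] - ab[2]*bc[1];
  nrm[1] = ab[2]*bc[0] - ab[0]*bc[2];
  nrm[2] = ab[0]*bc[1] - ab[1]*bc[0];
  double nn = std::sqrt(nrm[0]*nrm[0] + nrm[1]*nrm[1] + nrm[2]*nrm[2]);
  for (int k = 0; k < 3; ++k) nrm[k] /= (nn > 1e-12 ? nn : 1e-12);
  m[0] = nrm[1]*bc[2] - nrm[2]*bc[1];
  m[1] = nrm[2]*bc[0] - nrm[0]*bc[2];
  m[2] = nrm[0]*bc[1] - nrm[1]*bc[0];
  double th = ang * M_PI / 180.0, ph = tor * M_PI / 180.0;
  double d0 = -dist * std::cos(th);
  double d1 = dist * std::sin(th) * std::cos(ph);
  double d2 = dist * std::sin(th) * std::sin(ph);
  for (int k = 0; k < 3; ++k) out[k] = c[k] + d0 * bc[k] + d1 * m[k] + d2 * nrm[k];
}

// Chain gradients through hydrogen placement: given dL/d(H coords),
// accumulate into dL/d(parent heavy-atom coords) using a central-difference
// Jacobian of the NeRF placement (step 1e-5 A).
// [[Rcpp::export]]
NumericMatrix cpp_hplace_backprop(NumericMatrix xyz, IntegerVector ia,
                                  IntegerVector ib, IntegerVector ic,
                                  NumericVector dist, NumericVector ang,
                                  NumericVector tor, NumericMatrix dldh,
                                  int n_atoms) {
  NumericMatrix grad(n_atoms, 3);
  const double h = 1e-5;
  int nH = ia.size();
  for (int q = 0; q < nH; ++q) {
    double A[3], B[3], C[3];
    // NeRF reference order: a = xyz[ia], b = xyz[ic], c = xyz[ib]
    for (int k = 0; k < 3; ++k) {
      A[k] = xyz(ia[q] - 1, k);
      B[k] = xyz(ic[q] - 1, k);
      C[k] = xyz(ib[q] - 1, k);
    }
    double *refs[3] = {A, B, C};
    int gidx[3] = {ia[q] - 1, ic[q] - 1, ib[q] - 1};
    double hp[3], hm[3];
    for (int p = 0; p < 3; ++p) {
      for (int k = 0; k < 3; ++k) {
        double save = refs[p][k];
        refs[p][k] = save + h;
        nerf_one(A, B, C, dist[q], ang[q], tor[q], hp);
        refs[p][k] = save - h;
        nerf_one(A, B, C, dist[q], ang[q], tor[q], hm);
        refs[p][k] = save;
        double g = 0;
        for (int d = 0; d < 3; ++d)
          g += dldh(q, d) * (hp[d] - hm[d]) / (2 * h);
        grad(gidx[p], k) += g;
      }
    }
  }
  return grad;
}
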