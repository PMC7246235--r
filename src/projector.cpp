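#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Joseph-style length-weighted system matrix for a 2D parallel-beam geometry,
// returned as triplets for Matrix::sparseMatrix().
//
// Conventions (shared with the R side):
//  - image is n x n, voxel (i, j) has center (x, y) =
//    ((j - (n-1)/2) * vox_mm, (i - (n-1)/2) * vox_mm), 0-based indices;
//  - angle a in 0..n_ang-1 is theta = pi * a / n_ang; ray direction
//    d = (cos t, sin t), radial offset s along the normal u = (-sin t, cos t);
//  - ray index r = a + n_ang * b (an n_ang x n_rad sinogram, column-major);
//  - voxel index v = i + n * j (column-major image vector);
//  - weights are intersection lengths in cm (vox_mm is in mm).
//
// The ray is stepped along its driving axis (the axis with the larger
// direction component); the two voxels straddling the ray in the other axis
// receive linearly interpolated shares of the step length vox_mm/|d_major|.
// [[Rcpp::export]]
List cpp_system_triplets(int n, int n_ang, int n_rad, double bin_mm,
                         double vox_mm) {
  std::vector<int> ri, vi;
  std::vector<double> wv;
  const double half = (n - 1) / 2.0;
  const double rhalf = (n_rad - 1) / 2.0;
  ri.reserve((size_t)n_ang * n_rad * n * 2);
  vi.reserve(ri.capacity());
  wv.reserve(ri.capacity());

  for (int a = 0; a < n_ang; ++a) {
    const double theta = M_PI * a / n_ang;
    const double dx = std::cos(theta), dy = std::sin(theta);
    const double ux = -dy, uy = dx;
    for (int b = 0; b < n_rad; ++b) {
      const double s = (b - rhalf) * bin_mm;
      const int ray = a + n_ang * b;
      if (std::fabs(dx) >= std::fabs(dy)) {
        // drive along x (columns); step length in cm
        const double step = vox_mm / std::fabs(dx) / 10.0;
        for (int j = 0; j < n; ++j) {
          const double x = (j - half) * vox_mm;
          const double t = (x - s * ux) / dx;
          const double y = s * uy + t * dy;
          const double fi = y / vox_mm + half;
          const int i0 = (int)std::floor(fi);
          const double f = fi - i0;
          if (i0 >= 0 && i0 < n && f < 1.0) {
            ri.push_back(ray); vi.push_back(i0 + n * j);
            wv.push_back(step * (1.0 - f));
          }
          if (i0 + 1 >= 0 && i0 + 1 < n && f > 0.0) {
            ri.push_back(ray); vi.push_back(i0 + 1 + n * j);
            wv.push_back(step * f);
          }
        }
      } else {
        // drive along y (rows)
        const double step = vox_mm / std::fabs(dy) / 10.0;
        for (int i = 0; i < n; ++i) {
          const double y = (i - half) * vox_mm;
          const double t = (y - s * uy) / dy;
          const double x = s * ux + t * dx;
          const double fj = x / vox_mm + half;
          const int j0 = (int)std::floor(fj);
          const double f = fj - j0;
          if (j0 >= 0 && j0 < n && f < 1.0) {
            ri.push_back(ray); vi.push_back(i + n * j0);
            wv.push_back(step * (1.0 - f));
          }
          if (j0 + 1 >= 0 && j0 + 1 < n && f > 0.0) {
            ri.push_back(ray); vi.push_back(i + n * (j0 + 1));
            wv.push_back(step * f);
          }
        }
      }
    }
  }
  return List::create(_["i"] = ri, _["j"] = vi, _["x"] = wv);
}
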