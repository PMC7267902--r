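#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Count, for every voxel of the grid, the number of DISTINCT streamlines
// touching it. Coordinates arrive in world mm; invAffine maps world -> voxel
// coordinates with voxel centers at integers. Internally we shift by +0.5 so
// voxel i spans [i, i+1) ("u-space"), which makes floor() the point-to-voxel
// rule and lets the segment mode run a standard Amanatides-Woo traversal.
//
// segments = false : a streamline touches the voxels containing its points.
// segments = true  : a streamline touches every voxel its polyline crosses.
//
// Out-of-grid voxels are skipped (counted in nClipped for points); a
// streamline touching no in-grid voxel is tallied in nEmpty.

static inline long long linearIndex(int i, int j, int k,
                                    int nx, int ny) {
  return (long long)i + (long long)nx * ((long long)j + (long long)ny * k);
}

// [[Rcpp::export(name = ".voxelizeStreamlines")]]
IntegerVector voxelizeStreamlines(List streamlines, NumericMatrix invAffine,
                                  IntegerVector shape, bool segments) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  IntegerVector counts((R_xlen_t)nx * ny * nz);
  long long nClipped = 0, nEmpty = 0;

  const double a00 = invAffine(0,0), a01 = invAffine(0,1), a02 = invAffine(0,2), a03 = invAffine(0,3);
  const double a10 = invAffine(1,0), a11 = invAffine(1,1), a12 = invAffine(1,2), a13 = invAffine(1,3);
  const double a20 = invAffine(2,0), a21 = invAffine(2,1), a22 = invAffine(2,2), a23 = invAffine(2,3);

  std::unordered_set<long long> touched;

  for (R_xlen_t s = 0; s < streamlines.size(); ++s) {
    NumericMatrix pts = streamlines[s];
    const int n = pts.nrow();
    touched.clear();

    // transform to u-space
    std::vector<double> ux(n), uy(n), uz(n);
    for (int i = 0; i < n; ++i) {
      const double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
      ux[i] = a00 * x + a01 * y + a02 * z + a03 + 0.5;
      uy[i] = a10 * x + a11 * y + a12 * z + a13 + 0.5;
      uz[i] = a20 * x + a21 * y + a22 * z + a23 + 0.5;
    }

    // point containment (both modes count the points themselves)
    for (int i = 0; i < n; ++i) {
      const int vi = (int)std::floor(ux[i]);
      const int vj = (int)std::floor(uy[i]);
      const int vk = (int)std::floor(uz[i]);
      if (vi < 0 || vi >= nx || vj < 0 || vj >= ny || vk < 0 || vk >= nz) {
        ++nClipped;
        continue;
      }
      touched.insert(linearIndex(vi, vj, vk, nx, ny));
    }

    if (segments) {
      for (int i = 0; i + 1 < n; ++i) {
        double u0[3] = { ux[i], uy[i], uz[i] };
        double u1[3] = { ux[i + 1], uy[i + 1], uz[i + 1] };
        int c[3], e[3], step[3];
        double tMax[3], tDelta[3];
        long long maxIter = 3;
        for (int d = 0; d < 3; ++d) {
          c[d] = (int)std::floor(u0[d]);
          e[d] = (int)std::floor(u1[d]);
          const double dd = u1[d] - u0[d];
          if (dd > 0)      step[d] = 1;
          else if (dd < 0) step[d] = -1;
          else             step[d] = 0;
          if (step[d] != 0) {
            const double bound = (step[d] > 0) ? (c[d] + 1.0) : (double)c[d];
            tMax[d]   = (bound - u0[d]) / dd;
            tDelta[d] = std::fabs(1.0 / dd);
          } else {
            tMax[d]   = std::numeric_limits<double>::infinity();
            tDelta[d] = std::numeric_limits<double>::infinity();
          }
          maxIter += std::llabs((long long)e[d] - (long long)c[d]);
        }
        for (long long it = 0; it < maxIter; ++it) {
          if (c[0] >= 0 && c[0] < nx && c[1] >= 0 && c[1] < ny &&
              c[2] >= 0 && c[2] < nz)
            touched.insert(linearIndex(c[0], c[1], c[2], nx, ny));
          if (c[0] == e[0] && c[1] == e[1] && c[2] == e[2]) break;
          int axis = 0;
          if (tMax[1] < tMax[axis]) axis = 1;
          if (tMax[2] < tMax[axis]) axis = 2;
          c[axis]    += step[axis];
          tMax[axis] += tDelta[axis];
        }
      }
    }

    if (touched.empty()) ++nEmpty;
    for (long long idx : touched) counts[idx] += 1;
  }

  counts.attr("nClipped") = (double)nClipped;
  counts.attr("nEmpty")   = (double)nEmpty;
  return counts;
}
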