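// Texture-matrix accumulation on discretized 3D volumes.
//
// Volumes arrive as integer vectors in R's column-major layout with dims
// (nx, ny, nz); voxels outside the mask carry level 0, in-mask voxels carry
// levels 1..Ng. All matrices are accumulated over a caller-supplied set of
// direction offsets (the 13 unique 3D directions by default, chosen in R).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export(name = ".glcm_counts_cpp")]]
NumericMatrix glcm_counts_cpp(IntegerVector labels, IntegerVector dims,
                              IntegerMatrix directions, int ng, int distance) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix counts(ng, ng);
  for (int d = 0; d < directions.nrow(); ++d) {
    const int dx = directions(d, 0) * distance;
    const int dy = directions(d, 1) * distance;
    const int dz = directions(d, 2) * distance;
    for (int z = 0; z < nz; ++z) {
      const int z2 = z + dz;
      if (z2 < 0 || z2 >= nz) continue;
      for (int y = 0; y < ny; ++y) {
        const int y2 = y + dy;
        if (y2 < 0 || y2 >= ny) continue;
        for (int x = 0; x < nx; ++x) {
          const int x2 = x + dx;
          if (x2 < 0 || x2 >= nx) continue;
          const int a = labels[idx3(x, y, z, nx, ny)];
          if (a == 0) continue;
          const int b = labels[idx3(x2, y2, z2, nx, ny)];
          if (b == 0) continue;
          // symmetric accumulation: count the pair in both orders
          counts(a - 1, b - 1) += 1.0;
          counts(b - 1, a - 1) += 1.0;
        }
      }
    }
  }
  return counts;
}

// [[Rcpp::export(name = ".glrlm_counts_cpp")]]
NumericMatrix glrlm_counts_cpp(IntegerVector labels, IntegerVector dims,
                               IntegerMatrix directions, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int maxdim = std::max(nx, std::max(ny, nz));
  NumericMatrix counts(ng, maxdim);
  for (int d = 0; d < directions.nrow(); ++d) {
    const int dx = directions(d, 0), dy = directions(d, 1), dz = directions(d, 2);
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          const int a = labels[idx3(x, y, z, nx, ny)];
          if (a == 0) continue;
          // run starts where the previous voxel along the direction is
          // out-of-grid, out-of-mask, or a different level
          const int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz &&
              labels[idx3(xp, yp, zp, nx, ny)] == a) continue;
          int len = 1;
          int xc = x + dx, yc = y + dy, zc = z + dz;
          while (xc >= 0 && xc < nx && yc >= 0 && yc < ny && zc >= 0 && zc < nz &&
                 labels[idx3(xc, yc, zc, nx, ny)] == a) {
            ++len; xc += dx; yc += dy; zc += dz;
          }
          counts(a - 1, len - 1) += 1.0;
        }
      }
    }
  }
  return counts;
}

// [[Rcpp::export(name = ".gldm_counts_cpp")]]
NumericMatrix gldm_counts_cpp(IntegerVector labels, IntegerVector dims,
                              int ng, int alpha) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // dependence in 1..27 (centre + up to 26 qualifying neighbours)
  NumericMatrix counts(ng, 27);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const int a = labels[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        int dep = 1;
        for (int dz = -1; dz <= 1; ++dz) {
          const int z2 = z + dz;
          if (z2 < 0 || z2 >= nz) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            const int y2 = y + dy;
            if (y2 < 0 || y2 >= ny) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int x2 = x + dx;
              if (x2 < 0 || x2 >= nx) continue;
              const int b = labels[idx3(x2, y2, z2, nx, ny)];
              if (b == 0) continue;
              if (std::abs(a - b) <= alpha) ++dep;
            }
          }
        }
        counts(a - 1, dep - 1) += 1.0;
      }
    }
  }
  return counts;
}

// [[Rcpp::export(name = ".ngtdm_counts_cpp")]]
List ngtdm_counts_cpp(IntegerVector labels, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector s(ng), n(ng);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const int a = labels[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz) {
          const int z2 = z + dz;
          if (z2 < 0 || z2 >= nz) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            const int y2 = y + dy;
            if (y2 < 0 || y2 >= ny) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int x2 = x + dx;
              if (x2 < 0 || x2 >= nx) continue;
              const int b = labels[idx3(x2, y2, z2, nx, ny)];
              if (b == 0) continue;
              sum += b; ++cnt;
            }
          }
        }
        n[a - 1] += 1.0;
        if (cnt > 0) s[a - 1] += std::fabs(a - sum / cnt);
      }
    }
  }
  return List::create(_["s"] = s, _["n"] = n);
}

// [[Rcpp::export(name = ".glszm_counts_cpp")]]
NumericMatrix glszm_counts_cpp(IntegerVector labels, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz;
  std::vector<char> visited(nvox, 0);
  std::vector<std::pair<int, int>> zones; // (level, size)
  std::vector<int> stack;
  int max_size = 1;
  for (int start = 0; start < nvox; ++start) {
    const int a = labels[start];
    if (a == 0 || visited[start]) continue;
    // flood fill over the 26-connected same-level component
    int size = 0;
    stack.clear();
    stack.push_back(start);
    visited[start] = 1;
    while (!stack.empty()) {
      const int cur = stack.back(); stack.pop_back();
      ++size;
      const int x = cur % nx, y = (cur / nx) % ny, z = cur / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        const int z2 = z + dz;
        if (z2 < 0 || z2 >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int y2 = y + dy;
          if (y2 < 0 || y2 >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            const int x2 = x + dx;
            if (x2 < 0 || x2 >= nx) continue;
            const int nb = idx3(x2, y2, z2, nx, ny);
            if (!visited[nb] && labels[nb] == a) {
              visited[nb] = 1;
              stack.push_back(nb);
            }
          }
        }
      }
    }
    zones.push_back(std::make_pair(a, size));
    if (size > max_size) max_size = size;
  }
  NumericMatrix counts(ng, max_size);
  for (size_t i = 0; i < zones.size(); ++i)
    counts(zones[i].first - 1, zones[i].second - 1) += 1.0;
  return counts;
}

// [[Rcpp::export(name = ".surface_faces_cpp")]]
NumericVector surface_faces_cpp(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector faces(3); // exposed faces per axis
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        if (!mask[idx3(x, y, z, nx, ny)]) continue;
        faces[0] += (x == 0 || !mask[idx3(x - 1, y, z, nx, ny)]) +
                    (x == nx - 1 || !mask[idx3(x + 1, y, z, nx, ny)]);
        faces[1] += (y == 0 || !mask[idx3(x, y - 1, z, nx, ny)]) +
                    (y == ny - 1 || !mask[idx3(x, y + 1, z, nx, ny)]);
        faces[2] += (z == 0 || !mask[idx3(x, y, z - 1, nx, ny)]) +
                    (z == nz - 1 || !mask[idx3(x, y, z + 1, nx, ny)]);
      }
    }
  }
  return faces;
}
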