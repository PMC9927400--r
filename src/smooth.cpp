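// Separable 1D convolution along each axis with edge replication, used for
// the Gaussian-smoothed texture fields of the phantom generator.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".smooth_axis_cpp")]]
NumericVector smooth_axis_cpp(NumericVector a, IntegerVector dims, int axis,
                              NumericVector kernel) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int h = (kernel.size() - 1) / 2;
  NumericVector out(a.size());
  const int stride = (axis == 0) ? 1 : (axis == 1) ? nx : nx * ny;
  const int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  // iterate over all lines along `axis`
  const int n_other1 = (axis == 0) ? ny : nx;
  const int n_other2 = (axis == 2) ? ny : nz;
  const int s1 = (axis == 0) ? nx : 1;
  const int s2 = (axis == 2) ? nx : nx * ny;
  for (int j2 = 0; j2 < n_other2; ++j2) {
    for (int j1 = 0; j1 < n_other1; ++j1) {
      const int base = j1 * s1 + j2 * s2;
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int k = -h; k <= h; ++k) {
          int src = i + k;
          if (src < 0) src = 0;
          if (src >= n) src = n - 1;
          acc += kernel[k + h] * a[base + src * stride];
        }
        out[base + i * stride] = acc;
      }
    }
  }
  return out;
}
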