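#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Cubic median filter with edge replication (out-of-volume neighbors are
// clamped to the nearest voxel inside).
// [[Rcpp::export]]
NumericVector median3d_cpp(NumericVector vol, IntegerVector dim, int k) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int h = k / 2;
  NumericVector out(vol.size());
  std::vector<double> buf((size_t)k * k * k);
  const size_t mid = ((size_t)k * k * k) / 2;  // k odd, so k^3 is odd
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i2 = 0; i2 < d2; ++i2)
      for (int i1 = 0; i1 < d1; ++i1) {
        size_t nb = 0;
        for (int o3 = -h; o3 <= h; ++o3) {
          int j3 = std::min(std::max(i3 + o3, 0), d3 - 1);
          for (int o2 = -h; o2 <= h; ++o2) {
            int j2 = std::min(std::max(i2 + o2, 0), d2 - 1);
            size_t base = (size_t)d1 * (j2 + (size_t)d2 * j3);
            for (int o1 = -h; o1 <= h; ++o1) {
              int j1 = std::min(std::max(i1 + o1, 0), d1 - 1);
              buf[nb++] = vol[base + j1];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        out[i1 + (size_t)d1 * (i2 + (size_t)d2 * i3)] = buf[mid];
      }
  return out;
}
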