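#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Heavy-atom contact counting with a uniform grid (cell size = cutoff):
// every atom pair within <= cutoff whose residues differ contributes one
// count to n[i,j]. Returns triplets (i, j, count) with i < j, 1-based.
// [[Rcpp::export(name = ".count_contacts_cpp")]]
List count_contacts_cpp(NumericVector x, NumericVector y, NumericVector z,
                        IntegerVector res_index, double cutoff) {
  const int n = x.size();
  const double c2 = cutoff * cutoff;
  double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
  for (int i = 0; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (z[i] < zmin) zmin = z[i];
  }
  const double inv = 1.0 / cutoff;
  std::unordered_map<std::uint64_t, std::vector<int> > grid;
  grid.reserve(n * 2);
  std::vector<std::int64_t> cx(n), cy(n), cz(n);
  auto cell_id = [](std::int64_t a, std::int64_t b, std::int64_t c) {
    // pack 21-bit signed offsets; structures are << 2^20 cells wide
    return (std::uint64_t)((a + 1048576) | ((b + 1048576) << 21) |
                           ((c + 1048576) << 42));
  };
  for (int i = 0; i < n; ++i) {
    cx[i] = (std::int64_t)std::floor((x[i] - xmin) * inv);
    cy[i] = (std::int64_t)std::floor((y[i] - ymin) * inv);
    cz[i] = (std::int64_t)std::floor((z[i] - zmin) * inv);
    grid[cell_id(cx[i], cy[i], cz[i])].push_back(i);
  }
  std::unordered_map<std::uint64_t, int> counts;
  for (int i = 0; i < n; ++i) {
    const int ri = res_index[i];
    for (std::int64_t dx = -1; dx <= 1; ++dx)
      for (std::int64_t dy = -1; dy <= 1; ++dy)
        for (std::int64_t dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(cell_id(cx[i] + dx, cy[i] + dy, cz[i] + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;  // each unordered atom pair once
            const int rj = res_index[j];
            if (ri == rj) continue;
            const double ddx = x[i] - x[j], ddy = y[i] - y[j],
                         ddz = z[i] - z[j];
            if (ddx * ddx + ddy * ddy + ddz * ddz <= c2) {
              int a = ri < rj ? ri : rj, b = ri < rj ? rj : ri;
              ++counts[((std::uint64_t)a << 32) | (std::uint64_t)b];
            }
          }
        }
  }
  const size_t m = counts.size();
  IntegerVector oi(m), oj(m), ov(m);
  size_t k = 0;
  for (auto &kv : counts) {
    oi[k] = (int)(kv.first >> 32);
    oj[k] = (int)(kv.first & 0xffffffffu);
    ov[k] = kv.second;
    ++k;
  }
  return List::create(_["i"] = oi, _["j"] = oj, _["count"] = ov);
}
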