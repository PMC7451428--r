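#include <Rcpp.h>
#include <vector>
#include <array>
#include <unordered_map>

using namespace Rcpp;

// Connected-component labelling of a sparse voxel set on a 3D grid with
// 6/18/26-neighbour connectivity (breadth-first search over the set).
// `idx` holds 1-based linear indices into an array of dimensions `dim`.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(IntegerVector idx, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int m = idx.size();
  IntegerVector membership(m, 0);
  if (m == 0) return membership;
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::unordered_map<long long, int> pos;
  pos.reserve(m * 2);
  for (int i = 0; i < m; ++i) pos[(long long)idx[i] - 1] = i;

  std::vector<std::array<int, 3>> offs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int nzc = std::abs(dx) + std::abs(dy) + std::abs(dz);
        int maxo = connectivity == 6 ? 1 : (connectivity == 18 ? 2 : 3);
        if (nzc >= 1 && nzc <= maxo) offs.push_back({dx, dy, dz});
      }

  int comp = 0;
  std::vector<int> stack;
  for (int s = 0; s < m; ++s) {
    if (membership[s] != 0) continue;
    membership[s] = ++comp;
    stack.push_back(s);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      long long lin = (long long)idx[cur] - 1;
      int x = lin % nx, y = (lin / nx) % ny, z = lin / ((long long)nx * ny);
      for (auto& o : offs) {
        int X = x + o[0], Y = y + o[1], Z = z + o[2];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        long long nb = X + (long long)nx * Y + (long long)nx * ny * Z;
        auto it = pos.find(nb);
        if (it != pos.end() && membership[it->second] == 0) {
          membership[it->second] = comp;
          stack.push_back(it->second);
        }
      }
    }
  }
  return membership;
}
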