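// Vietoris-Rips persistent homology by boundary-matrix reduction over Z/2.
// Filtration values are simplex diameters (largest pairwise distance); the
// R wrapper converts to ball-radius units.  Dimensions 0..2 are supported,
// so simplices up to dimension 3 are enumerated.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct Simplex {
  double diam;
  int dim;
  std::array<uint16_t, 4> v;  // vertices, ascending; unused slots = 0xFFFF
};

inline uint64_t simplex_key(const std::array<uint16_t, 4>& v) {
  return (uint64_t)v[0] | ((uint64_t)v[1] << 16) | ((uint64_t)v[2] << 32) |
         ((uint64_t)v[3] << 48);
}

inline bool filt_less(const Simplex& a, const Simplex& b) {
  if (a.diam != b.diam) return a.diam < b.diam;
  if (a.dim != b.dim) return a.dim < b.dim;
  return a.v < b.v;
}

// symmetric difference of two ascending index lists (Z/2 column addition)
void add_column(std::vector<int>& col, const std::vector<int>& other) {
  std::vector<int> out;
  out.reserve(col.size() + other.size());
  std::set_symmetric_difference(col.begin(), col.end(), other.begin(),
                                other.end(), std::back_inserter(out));
  col.swap(out);
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix rips_pairs_cpp(NumericMatrix dist, int maxdim, double thresh) {
  const int n = dist.nrow();
  if (n > 65534) stop("too many points for the Rips engine (max 65534)");
  if (maxdim < 0 || maxdim > 2) stop("maxdim must be 0, 1 or 2");

  const uint16_t NONE = 0xFFFF;
  std::vector<Simplex> simp;

  // vertices
  for (int i = 0; i < n; ++i)
    simp.push_back({0.0, 0, {(uint16_t)i, NONE, NONE, NONE}});

  // neighbour lists under the diameter threshold
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (dist(i, j) <= thresh) {
        nb[i].push_back(j);
        simp.push_back({dist(i, j), 1, {(uint16_t)i, (uint16_t)j, NONE, NONE}});
      }

  if (maxdim >= 1) {  // triangles kill 1-cycles
    for (int i = 0; i < n; ++i)
      for (size_t aj = 0; aj < nb[i].size(); ++aj) {
        int j = nb[i][aj];
        for (size_t ak = aj + 1; ak < nb[i].size(); ++ak) {
          int k = nb[i][ak];
          if (dist(j, k) > thresh) continue;
          double d = std::max({dist(i, j), dist(i, k), dist(j, k)});
          simp.push_back({d, 2, {(uint16_t)i, (uint16_t)j, (uint16_t)k, NONE}});
        }
      }
  }
  if (maxdim >= 2) {  // tetrahedra kill 2-cycles
    for (int i = 0; i < n; ++i)
      for (size_t aj = 0; aj < nb[i].size(); ++aj) {
        int j = nb[i][aj];
        for (size_t ak = aj + 1; ak < nb[i].size(); ++ak) {
          int k = nb[i][ak];
          if (dist(j, k) > thresh) continue;
          for (size_t al = ak + 1; al < nb[i].size(); ++al) {
            int l = nb[i][al];
            if (dist(j, l) > thresh || dist(k, l) > thresh) continue;
            double d = std::max({dist(i, j), dist(i, k), dist(i, l),
                                 dist(j, k), dist(j, l), dist(k, l)});
            simp.push_back({d, 3,
                            {(uint16_t)i, (uint16_t)j, (uint16_t)k,
                             (uint16_t)l}});
          }
        }
      }
  }

  std::sort(simp.begin(), simp.end(), filt_less);
  const size_t m = simp.size();

  std::unordered_map<uint64_t, int> index_of;
  index_of.reserve(m * 2);
  for (size_t s = 0; s < m; ++s) index_of[simplex_key(simp[s].v)] = (int)s;

  // standard persistence reduction; reduced columns are kept only for
  // negative simplices (at most one per homology feature), so R is sparse
  std::vector<int> pivot_col(m, -1);   // row -> column having that pivot
  std::vector<int> paired_row(m, -1);  // column -> its pivot row
  std::vector<char> positive(m, 0);
  std::unordered_map<int, std::vector<int>> R;

  std::vector<int> col;
  for (size_t jcol = 0; jcol < m; ++jcol) {
    const Simplex& s = simp[jcol];
    col.clear();
    if (s.dim > 0) {
      std::array<uint16_t, 4> f;
      for (int drop = 0; drop <= s.dim; ++drop) {
        int pos = 0;
        f = {NONE, NONE, NONE, NONE};
        for (int t = 0; t <= s.dim; ++t)
          if (t != drop) f[pos++] = s.v[t];
        col.push_back(index_of[simplex_key(f)]);
      }
      std::sort(col.begin(), col.end());
    }
    while (!col.empty()) {
      int low = col.back();
      int other = pivot_col[low];
      if (other < 0) break;
      add_column(col, R[other]);
    }
    if (col.empty()) {
      positive[jcol] = 1;
    } else {
      int low = col.back();
      pivot_col[low] = (int)jcol;
      paired_row[jcol] = low;
      R[jcol].swap(col);
    }
    if (jcol % 65536 == 0) Rcpp::checkUserInterrupt();
  }

  std::vector<double> out_dim, out_birth, out_death;
  for (size_t jcol = 0; jcol < m; ++jcol) {
    if (paired_row[jcol] >= 0) {
      int row = paired_row[jcol];
      if (simp[jcol].diam > simp[row].diam) {
        out_dim.push_back(simp[row].dim);
        out_birth.push_back(simp[row].diam);
        out_death.push_back(simp[jcol].diam);
      }
    } else if (positive[jcol] && pivot_col[jcol] < 0 &&
               simp[jcol].dim <= maxdim) {
      out_dim.push_back(simp[jcol].dim);
      out_birth.push_back(simp[jcol].diam);
      out_death.push_back(R_PosInf);
    }
  }

  NumericMatrix res((int)out_dim.size(), 3);
  for (int r = 0; r < res.nrow(); ++r) {
    res(r, 0) = out_dim[r];
    res(r, 1) = out_birth[r];
    res(r, 2) = out_death[r];
  }
  colnames(res) = CharacterVector::create("dim", "birth", "death");
  return res;
}
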