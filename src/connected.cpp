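#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Neighbour offsets for 6-, 18- or 26-connectivity on a 3D lattice.
static std::vector<std::array<int, 3>> make_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nz = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

// Iterative flood fill over the foreground voxels of one binary volume.
// labels must be zero-initialised; returns the number of components.
static int label_volume(const int *fg, int *labels,
                        int nx, int ny, int nz,
                        const std::vector<std::array<int, 3>> &off,
                        std::vector<int> *sizes) {
  int n = nx * ny * nz;
  int cur = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!fg[i] || labels[i]) continue;
    ++cur;
    int sz = 0;
    stack.clear();
    stack.push_back(i);
    labels[i] = cur;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      ++sz;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (size_t k = 0; k < off.size(); ++k) {
        int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int u = xx + nx * (yy + ny * zz);
        if (fg[u] && !labels[u]) {
          labels[u] = cur;
          stack.push_back(u);
        }
      }
    }
    if (sizes) sizes->push_back(sz);
  }
  return cur;
}

//' @noRd
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector supra, IntegerVector dims,
                          int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((R_xlen_t)nx * ny * nz != supra.size())
    stop("length of supra does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  std::vector<std::array<int, 3>> off = make_offsets(connectivity);
  IntegerVector labels(supra.size(), 0);
  std::vector<int> fg(supra.size());
  for (R_xlen_t i = 0; i < supra.size(); ++i) fg[i] = supra[i] == TRUE;
  std::vector<int> sizes;
  int ncl = label_volume(fg.data(), INTEGER(labels), nx, ny, nz, off, &sizes);
  labels.attr("n_clusters") = ncl;
  labels.attr("sizes") = wrap(sizes);
  labels.attr("dim") = dims;
  return labels;
}

//' @noRd
// [[Rcpp::export(name = ".cc_max_extent")]]
IntegerVector cc_max_extent(LogicalMatrix supra, IntegerVector dims,
                            int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  if (supra.nrow() != n) stop("nrow(supra) does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  std::vector<std::array<int, 3>> off = make_offsets(connectivity);
  int P = supra.ncol();
  IntegerVector out(P);
  std::vector<int> fg(n), labels(n);
  for (int p = 0; p < P; ++p) {
    int any = 0;
    for (int i = 0; i < n; ++i) {
      fg[i] = supra(i, p) == TRUE;
      labels[i] = 0;
      any |= fg[i];
    }
    int best = 0;
    if (any) {
      std::vector<int> sizes;
      label_volume(fg.data(), labels.data(), nx, ny, nz, off, &sizes);
      for (size_t k = 0; k < sizes.size(); ++k)
        if (sizes[k] > best) best = sizes[k];
    }
    out[p] = best;
  }
  return out;
}

// Welch supra-threshold indicators for both directions, computed from the
// per-permutation group-1 moment matrices. qt() is evaluated only for
// entries passing the loosest critical value (df = n1 + n2 - 2).
//' @noRd
// [[Rcpp::export(name = ".welch_supra")]]
List welch_supra(NumericMatrix S1, NumericMatrix Q1,
                 NumericVector sy, NumericVector sy2,
                 double n1, double n2, double p_voxel) {
  int V = S1.nrow(), P = S1.ncol();
  LogicalMatrix dec(V, P), inc(V, P);
  double tloose = R::qt(1 - p_voxel, n1 + n2 - 2, 1, 0);
  for (int j = 0; j < P; ++j) {
    for (int i = 0; i < V; ++i) {
      double s1 = S1(i, j), q1 = Q1(i, j);
      double m1 = s1 / n1, m2 = (sy[i] - s1) / n2;
      double v1 = std::max(q1 - n1 * m1 * m1, 0.0) / (n1 - 1);
      double v2 = std::max((sy2[i] - q1) - n2 * m2 * m2, 0.0) / (n2 - 1);
      double a = v1 / n1, b = v2 / n2, se2 = a + b;
      if (se2 <= 0) continue;
      double t = (m1 - m2) / std::sqrt(se2);
      if (std::fabs(t) <= tloose) continue;
      double df = se2 * se2 / (a * a / (n1 - 1) + b * b / (n2 - 1));
      double tcrit = R::qt(1 - p_voxel, df, 1, 0);
      if (t > tcrit) inc(i, j) = true;
      else if (-t > tcrit) dec(i, j) = true;
    }
  }
  return List::create(_["decrease"] = dec, _["increase"] = inc);
}
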