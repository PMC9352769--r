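// Compiled kernels for the hot per-pixel loops: background noise synthesis and
// single-pass connected-component extraction with moment accumulation.
// Everything else in the package is vectorised R.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Gaussian background frame, quantised to integer grey levels and clamped to
// [0, maxval]. Seeded explicitly so lazy stacks can re-render bit-identical
// frames; the seed itself is drawn from R's RNG stream by the caller.
// [[Rcpp::export]]
IntegerMatrix cpp_gauss_frame(int nrow, int ncol, double mean, double sd,
                              double seed, int maxval = 255) {
  if (nrow <= 0 || ncol <= 0) stop("frame dimensions must be positive");
  IntegerMatrix out(nrow, ncol);
  std::mt19937_64 rng(static_cast<std::uint64_t>(seed));
  std::normal_distribution<double> norm(mean, sd);
  const R_xlen_t n = static_cast<R_xlen_t>(nrow) * ncol;
  int* p = INTEGER(out);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = std::round(norm(rng));
    if (v < 0) v = 0;
    if (v > maxval) v = maxval;
    p[i] = static_cast<int>(v);
  }
  return out;
}

namespace {
inline int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}
inline void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[ra] = rb;
}
}  // namespace

// Connected components of sub-threshold (dark-object convention) pixels with
// per-component pixel area, intensity-independent centroid, central second
// moments, mean intensity and bounding box. Two-pass union-find labelling;
// connectivity 4 or 8. Components smaller than min_area are dropped and the
// surviving ones relabelled 1..K in the returned label image.
// Row index = y (flow axis within the frame), column index = x.
// [[Rcpp::export]]
List cpp_components(IntegerMatrix img, double threshold, int connectivity = 8,
                    int min_area = 1) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = img.nrow(), nc = img.ncol();
  const int* px = INTEGER(img);
  std::vector<int> lab(static_cast<size_t>(nr) * nc, 0);
  std::vector<int> parent(1, 0);  // parent[0] unused
  int next = 0;

  // first pass: provisional labels, scanning column-major like R storage
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const size_t idx = static_cast<size_t>(c) * nr + r;
      if (!(px[idx] < threshold)) continue;
      int up = (r > 0 && lab[idx - 1]) ? lab[idx - 1] : 0;
      int left = (c > 0 && lab[idx - nr]) ? lab[idx - nr] : 0;
      int dl = 0, ul = 0;  // diagonal neighbours in previous column
      if (connectivity == 8 && c > 0) {
        if (r > 0 && lab[idx - nr - 1]) ul = lab[idx - nr - 1];
        if (r + 1 < nr && lab[idx - nr + 1]) dl = lab[idx - nr + 1];
      }
      int assigned = 0;
      for (int nb : {up, left, ul, dl}) {
        if (!nb) continue;
        if (!assigned) assigned = nb;
        else uf_union(parent, assigned, nb);
      }
      if (!assigned) {
        ++next;
        parent.push_back(next);
        assigned = next;
      }
      lab[idx] = assigned;
    }
  }

  // resolve equivalences, then accumulate raw moments
  std::vector<int> root(next + 1, 0);
  for (int i = 1; i <= next; ++i) root[i] = uf_find(parent, i);
  std::vector<int> compact(next + 1, 0);
  int ncomp = 0;
  for (int i = 1; i <= next; ++i)
    if (root[i] == i) compact[i] = ++ncomp;
  std::vector<double> area(ncomp + 1, 0), sx(ncomp + 1, 0), sy(ncomp + 1, 0),
      sxx(ncomp + 1, 0), syy(ncomp + 1, 0), sxy(ncomp + 1, 0),
      sint(ncomp + 1, 0);
  std::vector<int> rmin(ncomp + 1, nr + 1), rmax(ncomp + 1, 0),
      cmin(ncomp + 1, nc + 1), cmax(ncomp + 1, 0);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const size_t idx = static_cast<size_t>(c) * nr + r;
      if (!lab[idx]) continue;
      const int k = compact[root[lab[idx]]];
      lab[idx] = k;
      const double xr = r + 1.0, xc = c + 1.0;  // 1-based pixel centres
      area[k] += 1.0;
      sy[k] += xr; sx[k] += xc;
      syy[k] += xr * xr; sxx[k] += xc * xc; sxy[k] += xr * xc;
      sint[k] += px[idx];
      if (r + 1 < rmin[k]) rmin[k] = r + 1;
      if (r + 1 > rmax[k]) rmax[k] = r + 1;
      if (c + 1 < cmin[k]) cmin[k] = c + 1;
      if (c + 1 > cmax[k]) cmax[k] = c + 1;
    }
  }

  // drop sub-floor components and relabel
  std::vector<int> keep(ncomp + 1, 0);
  int nkeep = 0;
  for (int k = 1; k <= ncomp; ++k)
    if (area[k] >= min_area) keep[k] = ++nkeep;
  IntegerMatrix labels(nr, nc);
  int* pl = INTEGER(labels);
  for (size_t i = 0; i < lab.size(); ++i)
    pl[i] = lab[i] ? keep[lab[i]] : 0;

  NumericVector a(nkeep), cx(nkeep), cy(nkeep), mxx(nkeep), myy(nkeep),
      mxy(nkeep), mint(nkeep);
  IntegerVector r0(nkeep), r1(nkeep), c0(nkeep), c1(nkeep);
  for (int k = 1; k <= ncomp; ++k) {
    if (!keep[k]) continue;
    const int j = keep[k] - 1;
    const double n = area[k], mx = sx[k] / n, my = sy[k] / n;
    a[j] = n;
    cx[j] = mx; cy[j] = my;
    mxx[j] = sxx[k] / n - mx * mx;
    myy[j] = syy[k] / n - my * my;
    mxy[j] = sxy[k] / n - mx * my;
    mint[j] = sint[k] / n;
    r0[j] = rmin[k]; r1[j] = rmax[k]; c0[j] = cmin[k]; c1[j] = cmax[k];
  }
  DataFrame stats = DataFrame::create(
      _["label"] = seq_len(nkeep), _["area_px"] = a, _["cx"] = cx,
      _["cy"] = cy, _["mu_xx"] = mxx, _["mu_yy"] = myy, _["mu_xy"] = mxy,
      _["mean_intensity"] = mint, _["row_min"] = r0, _["row_max"] = r1,
      _["col_min"] = c0, _["col_max"] = c1);
  return List::create(_["labels"] = labels, _["stats"] = stats);
}
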