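#include <Rcpp.h>
using namespace Rcpp;

// Multiple-flow-direction accumulation.
// z: elevation matrix; ord: 0-based linear cell indices sorted by
// decreasing elevation (ties broken by index upstream in R). Each cell
// starts with its own area and passes its accumulated total to all strictly
// lower 8-neighbours with weights proportional to (drop/distance)^exponent.
// [[Rcpp::export]]
NumericMatrix mfd_accum_cpp(NumericMatrix z, double cell_size,
                            double exponent, IntegerVector ord) {
  const int nr = z.nrow(), nc = z.ncol();
  const double area = cell_size * cell_size;
  NumericMatrix acc(nr, nc);
  std::fill(acc.begin(), acc.end(), area);
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double diag = cell_size * std::sqrt(2.0);
  double w[8];
  int nb_r[8], nb_c[8];
  for (int k = 0; k < ord.size(); ++k) {
    const int idx = ord[k];
    const int c = idx / nr, r = idx % nr;  // column-major linear index
    const double zc = z(r, c);
    double wsum = 0.0;
    int nlow = 0;
    for (int m = 0; m < 8; ++m) {
      const int rr = r + dr[m], cc = c + dc[m];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const double zn = z(rr, cc);
      if (zn < zc) {
        const double dist = (dr[m] != 0 && dc[m] != 0) ? diag : cell_size;
        const double wk = std::pow((zc - zn) / dist, exponent);
        w[nlow] = wk;
        nb_r[nlow] = rr;
        nb_c[nlow] = cc;
        wsum += wk;
        ++nlow;
      }
    }
    if (nlow == 0 || wsum <= 0.0) continue;  // pit or flat: keep accumulation
    const double out = acc(r, c);
    for (int m = 0; m < nlow; ++m)
      acc(nb_r[m], nb_c[m]) += out * w[m] / wsum;
  }
  return acc;
}

// Nearest footprint cell search on the cell lattice. fr/fc are 0-based
// row/col indices of candidate footprint cells; fid the canopy id of each
// candidate. Squared distances are exact integers, so equidistant ties are
// well defined and resolve to the lowest canopy id. Candidates are bucketed
// on a coarse grid and scanned in expanding Chebyshev rings with a
// conservative lower bound, which keeps the search exact but local.
// Returns squared cell distance (in cells^2) and winning id per cell.
// [[Rcpp::export]]
List nearest_footprint_cpp(int nr, int nc, IntegerVector fr, IntegerVector fc,
                           IntegerVector fid) {
  const int nf = fr.size();
  const int B = 32;
  const int nbr = (nr + B - 1) / B, nbc = (nc + B - 1) / B;
  std::vector<std::vector<int> > bucket((size_t)nbr * nbc);
  for (int m = 0; m < nf; ++m)
    bucket[(size_t)(fr[m] / B) * nbc + fc[m] / B].push_back(m);
  const int max_ring = std::max(nbr, nbc);
  NumericMatrix d2(nr, nc);
  IntegerMatrix id(nr, nc);
  for (int c = 0; c < nc; ++c) {
    const int bc0 = c / B;
    for (int r = 0; r < nr; ++r) {
      const int br0 = r / B;
      long best = LONG_MAX;
      int bid = NA_INTEGER;
      for (int k = 0; k <= max_ring; ++k) {
        if (bid != NA_INTEGER) {
          // any candidate in ring k is at least (k-1)*B cells away
          const long lb = (long)(k - 1) * B;
          if (lb > 0 && lb * lb > best) break;
        }
        const int blo_r = br0 - k, bhi_r = br0 + k;
        const int blo_c = bc0 - k, bhi_c = bc0 + k;
        for (int bi = blo_r; bi <= bhi_r; ++bi) {
          if (bi < 0 || bi >= nbr) continue;
          const bool edge_row = (bi == blo_r || bi == bhi_r);
          for (int bj = blo_c; bj <= bhi_c; ++bj) {
            if (bj < 0 || bj >= nbc) continue;
            if (!edge_row && bj != blo_c && bj != bhi_c) continue;
            const std::vector<int> &cand = bucket[(size_t)bi * nbc + bj];
            if (cand.empty()) continue;
            // bucket bounding-box lower bound
            const int rlo = bi * B, rhi = std::min(rlo + B - 1, nr - 1);
            const int clo = bj * B, chi = std::min(clo + B - 1, nc - 1);
            const long dr = r < rlo ? rlo - r : (r > rhi ? r - rhi : 0);
            const long dc = c < clo ? clo - c : (c > chi ? c - chi : 0);
            if (dr * dr + dc * dc > best) continue;
            for (size_t t = 0; t < cand.size(); ++t) {
              const int m = cand[t];
              const long du = r - fr[m], dv = c - fc[m];
              const long dd = du * du + dv * dv;
              if (dd < best || (dd == best && fid[m] < bid)) {
                best = dd;
                bid = fid[m];
              }
            }
          }
        }
      }
      d2(r, c) = (double)best;
      id(r, c) = bid;
    }
  }
  return List::create(_["d2"] = d2, _["id"] = id);
}
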