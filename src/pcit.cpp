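#include <Rcpp.h>
using namespace Rcpp;

// PCIT edge elimination over all feature trios.
//
// For every unordered trio (x, y, z) the three first-order partial
// correlations are computed; the local tolerance is the mean of the
// partial-to-direct ratios over the trio's edges whose direct correlation
// exceeds `guard` in magnitude. An edge (x, y) is eliminated when, within
// some trio, |r_xy| < |eps * r_xz| and |r_xy| < |eps * r_yz| (strict: ties
// retain the edge). Trios containing a |r| = 1 pair, or with no valid
// tolerance term, are skipped. Returns the logical keep matrix: an entry is
// TRUE when the pair was never eliminated and its correlation is non-zero
// (|r| > guard).
// [[Rcpp::export]]
LogicalMatrix pcit_keep_cpp(NumericMatrix C, double guard) {
  const int n = C.nrow();
  LogicalMatrix elim(n, n);

  for (int x = 0; x < n - 2; ++x) {
    for (int y = x + 1; y < n - 1; ++y) {
      const double rxy = C(x, y);
      const double dxy = 1.0 - rxy * rxy;
      for (int z = y + 1; z < n; ++z) {
        const double rxz = C(x, z);
        const double ryz = C(y, z);
        const double dxz = 1.0 - rxz * rxz;
        const double dyz = 1.0 - ryz * ryz;
        if (dxy <= 0.0 || dxz <= 0.0 || dyz <= 0.0) continue;

        const double pxy = (rxy - rxz * ryz) / std::sqrt(dxz * dyz);
        const double pxz = (rxz - rxy * ryz) / std::sqrt(dxy * dyz);
        const double pyz = (ryz - rxy * rxz) / std::sqrt(dxy * dxz);

        double sum = 0.0; int cnt = 0;
        if (std::fabs(rxy) > guard) { sum += pxy / rxy; ++cnt; }
        if (std::fabs(rxz) > guard) { sum += pxz / rxz; ++cnt; }
        if (std::fabs(ryz) > guard) { sum += pyz / ryz; ++cnt; }
        if (cnt == 0) continue;
        const double eps = sum / cnt;

        const double axy = std::fabs(rxy), axz = std::fabs(rxz),
                     ayz = std::fabs(ryz);
        const double exy = std::fabs(eps * rxy), exz = std::fabs(eps * rxz),
                     eyz = std::fabs(eps * ryz);
        if (axy < exz && axy < eyz) elim(x, y) = true;
        if (axz < exy && axz < eyz) elim(x, z) = true;
        if (ayz < exy && ayz < exz) elim(y, z) = true;
      }
    }
  }

  LogicalMatrix keep(n, n);
  for (int x = 0; x < n; ++x)
    for (int y = x + 1; y < n; ++y) {
      bool k = !elim(x, y) && std::fabs(C(x, y)) > guard;
      keep(x, y) = k;
      keep(y, x) = k;
    }
  return keep;
}
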