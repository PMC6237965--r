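#include <Rcpp.h>
using namespace Rcpp;

// STARFM-style weighted neighbourhood prediction for one band.
//
// Inputs are double matrices on the fine grid with NA at nodata/QA-bad
// pixels: Lk/Mk are the fine and (resampled) coarse scenes of each input
// pair, Mp the coarse scene at the prediction date.  w is the moving-window
// half width (fine pixels), A the distance scale, thresh[k] the per-pair
// spectral-similarity threshold (2 * sd(Lk) / m).
//
// Rules (documented in the package vignette):
//  * If the central pixel's unfloored temporal difference T = |Mk - Mp| is
//    exactly 0 for some pair, the first-order relation is exact there and
//    L_k(center) is returned directly; likewise S = |Lk - Mk| = 0 returns
//    Mp(center).  This makes the temporal-identity case exact.
//  * Otherwise candidates within the window, valid in all three scenes of a
//    pair and spectrally similar to the central pixel (|L - L_center| <=
//    thresh), are pooled over pairs and combined with weights
//    1 / (S * T * D), S and T floored at 1 scaled-reflectance unit,
//    D = 1 + d / A.  Prediction = sum w * (Mp + L - Mk) / sum w.
//  * If no candidate qualifies, fall back to the central-pixel relation of
//    the pair with the smallest floored S * T; if no pair is valid at the
//    center, the output is NA.

// [[Rcpp::export]]
NumericMatrix starfm_band_cpp(List Lk, List Mk, NumericMatrix Mp,
                              int w, double A, NumericVector thresh) {
  int np = Lk.size();
  int nr = Mp.nrow(), nc = Mp.ncol();
  std::vector<NumericMatrix> L(np), M(np);
  for (int k = 0; k < np; k++) {
    L[k] = as<NumericMatrix>(Lk[k]);
    M[k] = as<NumericMatrix>(Mk[k]);
    if (L[k].nrow() != nr || L[k].ncol() != nc ||
        M[k].nrow() != nr || M[k].ncol() != nc)
      stop("fusion inputs disagree in geometry");
  }
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);

  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) {
      double mp_c = Mp(i, j);
      bool done = false;
      if (R_finite(mp_c)) {
        for (int k = 0; k < np && !done; k++) {
          double lc = L[k](i, j), mc = M[k](i, j);
          if (R_finite(lc) && R_finite(mc)) {
            if (mc == mp_c) { out(i, j) = lc; done = true; }
            else if (lc == mc) { out(i, j) = mp_c; done = true; }
          }
        }
      }
      if (done) continue;

      double num = 0.0, den = 0.0;
      int i0 = std::max(0, i - w), i1 = std::min(nr - 1, i + w);
      int j0 = std::max(0, j - w), j1 = std::min(nc - 1, j + w);
      for (int k = 0; k < np; k++) {
        double lc = L[k](i, j);
        if (!R_finite(lc)) continue; // similarity undefined for this pair
        for (int ii = i0; ii <= i1; ii++) {
          for (int jj = j0; jj <= j1; jj++) {
            double l = L[k](ii, jj), m = M[k](ii, jj), mp = Mp(ii, jj);
            if (!R_finite(l) || !R_finite(m) || !R_finite(mp)) continue;
            if (std::fabs(l - lc) > thresh[k]) continue;
            double S = std::max(std::fabs(l - m), 1.0);
            double T = std::max(std::fabs(m - mp), 1.0);
            double di = ii - i, dj = jj - j;
            double D = 1.0 + std::sqrt(di * di + dj * dj) / A;
            double wgt = 1.0 / (S * T * D);
            num += wgt * (mp + l - m);
            den += wgt;
          }
        }
      }
      if (den > 0) { out(i, j) = num / den; continue; }

      double best = R_PosInf, pred = NA_REAL;
      if (R_finite(mp_c)) {
        for (int k = 0; k < np; k++) {
          double lc = L[k](i, j), mc = M[k](i, j);
          if (!R_finite(lc) || !R_finite(mc)) continue;
          double S = std::max(std::fabs(lc - mc), 1.0);
          double T = std::max(std::fabs(mc - mp_c), 1.0);
          if (S * T < best) { best = S * T; pred = lc + mp_c - mc; }
        }
      }
      out(i, j) = pred;
    }
  }
  return out;
}
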