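#include <Rcpp.h>
using namespace Rcpp;

// Blockwise coordinate-descent solver for the graphical lasso.
// Operates in place on the working covariance W and the regression
// coefficient matrix B (beta for column j lives in B(,j), with B(j,j)=0),
// so callers can warm-start along a penalty path.

static double soft(double x, double lam) {
  if (x > lam) return x - lam;
  if (x < -lam) return x + lam;
  return 0.0;
}

// [[Rcpp::export(name = ".glasso_cd")]]
List glasso_cd(NumericMatrix S, double rho, NumericMatrix W0, NumericMatrix B0,
               double tol, int max_iter, double cd_tol, int cd_max_iter) {
  int p = S.nrow();
  NumericMatrix W(clone(W0));
  NumericMatrix B(clone(B0));
  double off_scale = 0.0;
  int n_off = 0;
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) { off_scale += std::fabs(S(i, j)); ++n_off; }
  off_scale = n_off > 0 ? off_scale / n_off : 1.0;
  if (off_scale == 0.0) off_scale = 1.0;

  bool converged = false;
  for (int it = 0; it < max_iter; ++it) {
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      // lasso on column j: minimize 0.5 b'W11 b - s12'b + rho |b|_1
      for (int cd = 0; cd < cd_max_iter; ++cd) {
        double cd_delta = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double resid = S(k, j);
          for (int l = 0; l < p; ++l) {
            if (l == j || l == k) continue;
            resid -= W(k, l) * B(l, j);
          }
          double bnew = soft(resid, rho) / W(k, k);
          double d = std::fabs(bnew - B(k, j));
          if (d > cd_delta) cd_delta = d;
          B(k, j) = bnew;
        }
        if (cd_delta < cd_tol) break;
      }
      // w12 = W11 beta
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        double w = 0.0;
        for (int l = 0; l < p; ++l) {
          if (l == j) continue;
          w += W(k, l) * B(l, j);
        }
        double d = std::fabs(w - W(k, j));
        if (d > delta) delta = d;
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    if (delta < tol * off_scale) { converged = true; break; }
  }
  return List::create(_["W"] = W, _["B"] = B, _["converged"] = converged);
}
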