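// Artificial-centering hit-and-run over the steady-state flux polytope,
// parameterized in null-space coordinates so S v = 0 holds by construction.
// The chain runs on the free (non-fixed) reactions only; v = v0 + N a with
// N an orthonormal basis of null(S_free).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {
// Deterministic uniforms straight from the engine state: identical on every
// platform for a given seed, unlike std::uniform_real_distribution.
inline double runif53(std::mt19937_64 &eng) {
  return (eng() >> 11) * (1.0 / 9007199254740992.0); // [0, 1)
}
}

// [[Rcpp::export(name = ".achr_chain")]]
arma::mat achr_chain(const arma::mat &N,            // n_free x d
                     const arma::vec &v0,           // n_free
                     const arma::mat &warmup_alpha, // d x n_warm
                     const arma::vec &lb,
                     const arma::vec &ub,
                     int n_points, int n_steps, double seed) {
  const arma::uword n = v0.n_elem, d = N.n_cols,
                    n_warm = warmup_alpha.n_cols;
  std::mt19937_64 eng(static_cast<std::uint64_t>(seed));
  arma::vec center = arma::mean(warmup_alpha, 1);
  double center_count = static_cast<double>(n_warm);
  arma::vec alpha = center;
  arma::vec v = v0 + N * alpha;
  arma::mat out(n_points, n);
  const double dir_tol = 1e-12, comp_tol = 1e-10;

  for (int p = 0; p < n_points; ++p) {
    for (int s = 0; s < n_steps; ++s) {
      arma::uword r = static_cast<arma::uword>(runif53(eng) * n_warm);
      if (r >= n_warm) r = n_warm - 1;
      arma::vec u = warmup_alpha.col(r) - center;
      double nu = arma::norm(u);
      if (nu < dir_tol) continue;
      u /= nu;
      arma::vec dv = N * u;
      // chord limits from the box constraints on v
      double tmin = -std::numeric_limits<double>::infinity();
      double tmax = std::numeric_limits<double>::infinity();
      for (arma::uword j = 0; j < n; ++j) {
        double dj = dv(j);
        if (std::fabs(dj) < comp_tol) continue;
        double lo = (lb(j) - v(j)) / dj, hi = (ub(j) - v(j)) / dj;
        if (dj > 0) {
          if (lo > tmin) tmin = lo;
          if (hi < tmax) tmax = hi;
        } else {
          if (hi > tmin) tmin = hi;
          if (lo < tmax) tmax = lo;
        }
      }
      if (!std::isfinite(tmin) || !std::isfinite(tmax) || tmax - tmin < dir_tol)
        continue;
      double t = tmin + (tmax - tmin) * runif53(eng);
      alpha += t * u;
      v += t * dv;
      center += (alpha - center) / (center_count + 1.0);
      center_count += 1.0;
    }
    v = v0 + N * alpha; // re-anchor: kills incremental round-off drift
    for (arma::uword j = 0; j < n; ++j)
      v(j) = std::min(std::max(v(j), lb(j)), ub(j));
    out.row(p) = v.t();
  }
  return out;
}
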