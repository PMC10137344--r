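#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Gamete formation under the Haldane model: per chromosome the crossover
// count is Poisson(length in Morgans), crossover positions are uniform and
// there is no interference or mutation.  Uses R's RNG so results are
// reproducible under set.seed().
//
// hap1/hap2: parent haplotype matrices (parents x markers, 0/1).
// parent_idx: 0-based row of the parent transmitting each gamete.
// chr_start: 0-based first marker index of each chromosome.
// chr_size: number of markers per chromosome.
// chr_length: chromosome genetic lengths in Morgans.
// pos: genetic position of every marker within its chromosome (Morgans).
// [[Rcpp::export]]
IntegerMatrix cpp_make_gametes(const IntegerMatrix& hap1,
                               const IntegerMatrix& hap2,
                               const IntegerVector& parent_idx,
                               const IntegerVector& chr_start,
                               const IntegerVector& chr_size,
                               const NumericVector& chr_length,
                               const NumericVector& pos) {
  const int n_gam = parent_idx.size();
  const int n_chr = chr_start.size();
  const int M = hap1.ncol();
  IntegerMatrix out(n_gam, M);
  std::vector<double> xo;

  for (int g = 0; g < n_gam; ++g) {
    const int p = parent_idx[g];
    for (int c = 0; c < n_chr; ++c) {
      const int s = chr_start[c], m = chr_size[c];
      const double L = chr_length[c];
      int cur = (unif_rand() < 0.5) ? 0 : 1;   // starting strand
      int k = (L > 0.0) ? (int) R::rpois(L) : 0;
      if (k == 0) {
        if (cur == 0)
          for (int j = 0; j < m; ++j) out(g, s + j) = hap1(p, s + j);
        else
          for (int j = 0; j < m; ++j) out(g, s + j) = hap2(p, s + j);
        continue;
      }
      xo.resize(k);
      for (int i = 0; i < k; ++i) xo[i] = unif_rand() * L;
      std::sort(xo.begin(), xo.end());
      int nxt = 0;
      for (int j = 0; j < m; ++j) {
        const double pj = pos[s + j];
        while (nxt < k && xo[nxt] <= pj) { cur = 1 - cur; ++nxt; }
        out(g, s + j) = (cur == 0) ? hap1(p, s + j) : hap2(p, s + j);
      }
    }
  }
  return out;
}

static inline double rscinvchi2(double df, double scale) {
  // scaled inverse chi-squared draw: df*scale / chisq(df)
  return df * scale / R::rchisq(df);
}

// Single-site Gibbs sampler for BayesB: y = 1*mu + W beta delta + e,
// beta_j | delta_j=1 ~ N(0, sigma2_j), sigma2_j ~ scaled-inv-chisq(df, S),
// P(delta_j = 0) = pi.  Residual variance has a flat scaled-inv-chisq prior.
// fix_common_var freezes every marker variance at `scale` and the residual
// variance at sigma2e_init (used for the ridge-equivalence cross-check).
// [[Rcpp::export]]
List cpp_bayesb(const NumericVector& y,
                const NumericMatrix& W,
                double pi_zero,
                int n_iter,
                int n_burn,
                double df,
                double scale,
                double sigma2e_init,
                bool fix_common_var) {
  const int n = W.nrow(), m = W.ncol();
  NumericVector e = clone(y);
  std::vector<double> beta(m, 0.0), sig2(m, scale);
  std::vector<double> cj(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += W(i, j) * W(i, j);
    cj[j] = s;
  }
  double mu = Rcpp::mean(y);
  for (int i = 0; i < n; ++i) e[i] -= mu;
  double sigma2e = sigma2e_init;

  NumericVector beta_sum(m), incl_sum(m);
  double mu_sum = 0.0;
  int n_keep = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept: full conditional N(mu + mean(e), sigma2e/n)
    double emean = 0.0;
    for (int i = 0; i < n; ++i) emean += e[i];
    emean /= n;
    const double mu_new = mu + emean + R::norm_rand() * std::sqrt(sigma2e / n);
    const double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    double* ep = REAL(e);
    for (int j = 0; j < m; ++j) {
      const double c = cj[j];
      if (c <= 0.0) { beta[j] = 0.0; continue; }
      const double* wj = &W(0, j);
      // r = W_j' (e + W_j beta_j)
      double r = 0.0;
      if (beta[j] != 0.0) {
        for (int i = 0; i < n; ++i) r += wj[i] * (ep[i] + wj[i] * beta[j]);
      } else {
        for (int i = 0; i < n; ++i) r += wj[i] * ep[i];
      }
      double s2 = sig2[j];
      int del = 1;
      if (pi_zero > 0.0) {
        // log marginal likelihood of r under delta = 1 / delta = 0
        const double v1 = c * c * s2 + c * sigma2e;
        const double v0 = c * sigma2e;
        const double l1 = -0.5 * (std::log(v1) + r * r / v1) + std::log(1.0 - pi_zero);
        const double l0 = -0.5 * (std::log(v0) + r * r / v0) + std::log(pi_zero);
        const double p1 = 1.0 / (1.0 + std::exp(l0 - l1));
        del = (unif_rand() < p1) ? 1 : 0;
      }
      double b_new = 0.0;
      if (del == 1) {
        const double prec = c + sigma2e / s2;
        b_new = r / prec + R::norm_rand() * std::sqrt(sigma2e / prec);
      }
      if (b_new != beta[j]) {
        const double d = b_new - beta[j];
        for (int i = 0; i < n; ++i) ep[i] -= wj[i] * d;
        beta[j] = b_new;
      }
      if (!fix_common_var) {
        sig2[j] = (del == 1)
          ? rscinvchi2(df + 1.0, (df * scale + beta[j] * beta[j]) / (df + 1.0))
          : rscinvchi2(df, scale);
      }
      if (it >= n_burn) {
        beta_sum[j] += beta[j];
        incl_sum[j] += del;
      }
    }

    if (!fix_common_var) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma2e = rscinvchi2((double) n, sse / n);
    }
    if (it >= n_burn) { mu_sum += mu; ++n_keep; }

    for (int i = 0; i < n; ++i) {
      if (!R_finite(e[i])) stop("BayesB chain diverged (non-finite residual)");
    }
  }

  const double denom = std::max(n_keep, 1);
  NumericVector bm(m), ip(m);
  for (int j = 0; j < m; ++j) {
    bm[j] = beta_sum[j] / denom;
    ip[j] = incl_sum[j] / denom;
  }
  return List::create(_["beta_mean"] = bm,
                      _["inclusion_prob"] = ip,
                      _["mu_mean"] = mu_sum / denom);
}
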