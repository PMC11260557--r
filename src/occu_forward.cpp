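#include <Rcpp.h>
using namespace Rcpp;

// Marginalized dynamic-occupancy log-likelihood and its gradient on the
// probability scale, vectorized over sites.
//
// The latent occupancy chain z_t in {0,1} is never sampled: per site the
// forward recursion runs over the 2-state hidden Markov chain with
//   initial law      (1 - psi1, psi1)
//   transition rows  z=0: (1-gamma, gamma),  z=1: (epsilon, 1-epsilon)
//   emissions        z=1: p^d (1-p)^(n-d) over the n surveyed occasions
//                         with d detections in the period
//                    z=0: 1 if d == 0, else 0
// Periods with no surveyed occasion contribute emission 1 in both states.
// Detection probability p is site-level (occasion-constant), so (n, d)
// per site-period are sufficient. Gradients are exact, via the scaled
// forward-backward recursions.
//
// ndet, nocc: n_sites x T; gamma, eps: n_sites x (T-1); psi1, p: n_sites.
// Returns total loglik and d loglik / d {psi1, p, gamma, eps}.
// [[Rcpp::export(rng = false)]]
List occu_forward_grad(NumericMatrix ndet, NumericMatrix nocc,
                       NumericVector psi1, NumericVector p,
                       NumericMatrix gamma_, NumericMatrix eps_) {
  const int n = ndet.nrow(), T = ndet.ncol();
  NumericVector d_psi1(n), d_p(n);
  NumericMatrix d_gamma(n, std::max(T - 1, 0)), d_eps(n, std::max(T - 1, 0));
  double ll = 0.0;
  bool impossible = false;

  std::vector<double> m0(T), m1(T), at0(T), at1(T), ft0(T), ft1(T), c(T);

  for (int i = 0; i < n && !impossible; ++i) {
    const double pi1 = psi1[i], pd = p[i];
    // emissions
    for (int t = 0; t < T; ++t) {
      const double nn = nocc(i, t), dd = ndet(i, t);
      if (nn <= 0.0) {
        m0[t] = 1.0; m1[t] = 1.0;
      } else {
        m0[t] = (dd > 0.0) ? 0.0 : 1.0;
        m1[t] = std::pow(pd, dd) * std::pow(1.0 - pd, nn - dd);
      }
    }
    // scaled forward pass: ft = pre-emission, at = post-emission (normalized)
    ft0[0] = 1.0 - pi1; ft1[0] = pi1;
    double lli = 0.0;
    bool site_zero = false;
    for (int t = 0; t < T; ++t) {
      if (t > 0) {
        const double g = gamma_(i, t - 1), e = eps_(i, t - 1);
        ft0[t] = at0[t - 1] * (1.0 - g) + at1[t - 1] * e;
        ft1[t] = at0[t - 1] * g + at1[t - 1] * (1.0 - e);
      }
      double a0 = ft0[t] * m0[t], a1 = ft1[t] * m1[t];
      const double ct = a0 + a1;
      if (!(ct > 0.0)) { site_zero = true; break; }
      c[t] = ct;
      at0[t] = a0 / ct; at1[t] = a1 / ct;
      lli += std::log(ct);
    }
    if (site_zero) { impossible = true; break; }
    ll += lli;

    // scaled backward pass, accumulating gradients
    double b0 = 1.0, b1 = 1.0;  // bhat_T
    // p-gradient contribution at t = T-1 (0-based)
    double gp = 0.0;
    {
      const int t = T - 1;
      const double nn = nocc(i, t), dd = ndet(i, t);
      if (nn > 0.0 && m1[t] > 0.0) {
        gp += ft1[t] * b1 * m1[t] * (dd / pd - (nn - dd) / (1.0 - pd)) / c[t];
      }
    }
    for (int t = T - 2; t >= 0; --t) {
      const double g = gamma_(i, t), e = eps_(i, t);
      const double w0 = m0[t + 1] * b0, w1 = m1[t + 1] * b1;
      d_gamma(i, t) = at0[t] * (w1 - w0) / c[t + 1];
      d_eps(i, t) = at1[t] * (w0 - w1) / c[t + 1];
      // bhat_t = P_t (m_{t+1} o bhat_{t+1}) / c_{t+1}
      const double nb0 = ((1.0 - g) * w0 + g * w1) / c[t + 1];
      const double nb1 = (e * w0 + (1.0 - e) * w1) / c[t + 1];
      b0 = nb0; b1 = nb1;
      const double nn = nocc(i, t), dd = ndet(i, t);
      if (nn > 0.0 && m1[t] > 0.0) {
        gp += ft1[t] * b1 * m1[t] * (dd / pd - (nn - dd) / (1.0 - pd)) / c[t];
      }
    }
    d_psi1[i] = (m1[0] * b1 - m0[0] * b0) / c[0];
    d_p[i] = gp;
  }

  if (impossible) {
    return List::create(_["loglik"] = R_NegInf,
                        _["d_psi1"] = NumericVector(n),
                        _["d_p"] = NumericVector(n),
                        _["d_gamma"] = NumericMatrix(n, std::max(T - 1, 0)),
                        _["d_eps"] = NumericMatrix(n, std::max(T - 1, 0)));
  }
  return List::create(_["loglik"] = ll, _["d_psi1"] = d_psi1, _["d_p"] = d_p,
                      _["d_gamma"] = d_gamma, _["d_eps"] = d_eps);
}
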