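#include <Rcpp.h>
using namespace Rcpp;

// Metropolis Monte Carlo on a binary (+1/-1) sequence under the quadratic
// Hamiltonian H(s) = (kappa/2) * (sum_i D_i s_i - tau_star)^2.
//
// Proposals flip the spin at a uniformly chosen site; a proposal is accepted
// with probability min(1, exp(-dH)). dH is computed incrementally in O(1) by
// maintaining the running trait value tau = sum_i D_i s_i. The run stops after
// n_accept accepted flips and returns the final sequence together with the
// log of accepted flip sites (1-based), so a caller can replay the trajectory.
//
// Uses R's RNG: determinism is governed by set.seed() on the R side.
//
// [[Rcpp::export]]
List metropolis_run_cpp(IntegerVector seq, NumericVector D, double kappa,
                        double tau_star, int n_accept, double stall_cap) {
  const int L = seq.size();
  if (D.size() != L) stop("length of D must match sequence length");
  IntegerVector s = clone(seq);

  double tau = 0.0;
  for (int i = 0; i < L; ++i) tau += D[i] * s[i];

  std::vector<int> flips;
  flips.reserve(n_accept > 0 ? n_accept : 0);

  double n_prop = 0.0;
  double consec_rej = 0.0;
  int acc = 0;

  while (acc < n_accept) {
    int j = (int)(unif_rand() * L);
    if (j == L) j = L - 1; // guard against unif_rand() == 1.0
    n_prop += 1.0;

    const double tau_new = tau - 2.0 * D[j] * s[j];
    const double d_old = tau - tau_star;
    const double d_new = tau_new - tau_star;
    const double dH = 0.5 * kappa * (d_new * d_new - d_old * d_old);

    bool accept = (dH <= 0.0) || (unif_rand() < std::exp(-dH));
    if (accept) {
      s[j] = -s[j];
      tau = tau_new;
      flips.push_back(j + 1);
      ++acc;
      consec_rej = 0.0;
    } else {
      consec_rej += 1.0;
      if (consec_rej >= stall_cap)
        stop("Metropolis sampler stalled: %.0f consecutive rejected proposals "
             "(selection too strong to reach the requested number of accepted "
             "mutations)", consec_rej);
    }
  }

  return List::create(_["seq"] = s,
                      _["flips"] = wrap(flips),
                      _["n_proposals"] = n_prop,
                      _["trait"] = tau);
}
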