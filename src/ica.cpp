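// Sequential-sampling Bayesian ICA learner.  Per 5 ms bin: enumerate
// the 2^p joint source configurations, score each by the Bernoulli
// likelihood of the current input bin times the independent-Bernoulli
// source prior, sample one configuration, then take a stochastic
// gradient step on the estimated response-probability matrix Q~.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// per-state spike probability p_i for one neuron given kernel sums A
static inline double p_spike(double ro_dt, const double* qrow, int Lstride,
                             const std::vector<double>& A, int p) {
  double prod = 1.0 - ro_dt;
  for (int mu = 0; mu < p; ++mu) {
    double f = 1.0 - qrow[(size_t)mu * Lstride] * A[mu];
    if (f < 1e-12) f = 1e-12;
    prod *= f;
  }
  double pi = 1.0 - prod;
  if (pi < 1e-12) pi = 1e-12;
  if (pi > 1.0 - 1e-12) pi = 1.0 - 1e-12;
  return pi;
}

// [[Rcpp::export]]
List cpp_ica_run(IntegerMatrix x, NumericMatrix Q0, NumericMatrix Qsample,
                 NumericVector phi, double ro_dt, double rs_dt,
                 double eta, bool ideal, bool include_current,
                 int snap_every) {
  const int L = x.nrow(), K = x.ncol(), p = Q0.ncol();
  const int nk = phi.size();
  if (p > 12) stop("p > 12: joint source enumeration is not feasible");
  const int nstates = 1 << p;

  NumericMatrix Q = clone(Q0);          // learned matrix
  // Qs: matrix used for sampling (true Q in ideal mode, else the
  // evolving estimate Q itself)
  NumericMatrix Qs = ideal ? Qsample : Q;

  // ring buffer of sampled source states, y[mu][k mod nk]
  std::vector<std::vector<int>> yring(p, std::vector<int>(nk, 0));
  IntegerMatrix Y(p, K);
  std::vector<double> Ahist(p), A(p), Aupd(p);
  std::vector<double> logw(nstates), pr(nstates);
  NumericVector loglik(K);
  std::vector<NumericMatrix> snaps;
  std::vector<int> snap_bins;
  const double log_rs = std::log(rs_dt), log_1mrs = std::log(1.0 - rs_dt);

  for (int k = 0; k < K; ++k) {
    // kernel sums from past samples only: A_mu = sum_{k'>=1} phi_k' y^{k-k'}
    for (int mu = 0; mu < p; ++mu) {
      double a = 0;
      for (int kp = 1; kp < nk; ++kp) {
        int kk = k - kp;
        if (kk < 0) break;
        a += phi[kp] * yring[mu][kk % nk];
      }
      Ahist[mu] = a;
    }
    // score all joint configurations of the current bin
    double best = -INFINITY;
    for (int s = 0; s < nstates; ++s) {
      for (int mu = 0; mu < p; ++mu)
        A[mu] = Ahist[mu] + ((s >> mu) & 1) * phi[0];
      double lw = 0;
      for (int mu = 0; mu < p; ++mu)
        lw += ((s >> mu) & 1) ? log_rs : log_1mrs;
      for (int i = 0; i < L; ++i) {
        double pi = p_spike(ro_dt, &Qs[i], L, A, p);
        lw += x(i, k) ? std::log(pi) : std::log(1.0 - pi);
      }
      logw[s] = lw;
      if (lw > best) best = lw;
    }
    double tot = 0;
    for (int s = 0; s < nstates; ++s) { pr[s] = std::exp(logw[s] - best); tot += pr[s]; }
    double u = unif_rand() * tot, cum = 0;
    int pick = nstates - 1;
    for (int s = 0; s < nstates; ++s) { cum += pr[s]; if (u <= cum) { pick = s; break; } }
    for (int mu = 0; mu < p; ++mu) {
      int yv = (pick >> mu) & 1;
      yring[mu][k % nk] = yv;
      Y(mu, k) = yv;
    }
    loglik[k] = logw[pick];

    // gradient step on Q~ using the sampled history (optionally
    // including the current sample)
    for (int mu = 0; mu < p; ++mu)
      Aupd[mu] = Ahist[mu] +
        (include_current ? ((pick >> mu) & 1) * phi[0] : 0.0);
    for (int i = 0; i < L; ++i) {
      double pi = p_spike(ro_dt, &Q[i], L, Aupd, p);
      double base = x(i, k) ? (1.0 - pi) / pi : -1.0;
      for (int mu = 0; mu < p; ++mu) {
        double a = Aupd[mu];
        if (a <= 0) continue;
        double denom = 1.0 - Q(i, mu) * a;
        if (denom < 1e-6) denom = 1e-6;
        double q = Q(i, mu) + eta * base * a / denom;
        Q(i, mu) = q < 0 ? 0 : (q > 1 ? 1 : q);
      }
    }

    if (snap_every > 0 && (k + 1) % snap_every == 0) {
      snaps.push_back(clone(Q));
      snap_bins.push_back(k + 1);
    }
  }

  return List::create(_["Q"] = Q, _["Y"] = Y, _["loglik"] = loglik,
                      _["snapshots"] = wrap(snaps),
                      _["snap_bins"] = wrap(snap_bins));
}

// single-bin posterior over the 2^p joint source configurations
// (exposed for equivalence tests against the R enumeration oracle)
// [[Rcpp::export]]
NumericVector cpp_ica_state_probs(IntegerVector xk, NumericMatrix Qs,
                                  NumericVector phi, NumericVector Ahist,
                                  double ro_dt, double rs_dt) {
  const int L = xk.size(), p = Qs.ncol();
  const int nstates = 1 << p;
  std::vector<double> A(p), logw(nstates);
  const double log_rs = std::log(rs_dt), log_1mrs = std::log(1.0 - rs_dt);
  double best = -INFINITY;
  for (int s = 0; s < nstates; ++s) {
    for (int mu = 0; mu < p; ++mu)
      A[mu] = Ahist[mu] + ((s >> mu) & 1) * phi[0];
    double lw = 0;
    for (int mu = 0; mu < p; ++mu)
      lw += ((s >> mu) & 1) ? log_rs : log_1mrs;
    for (int i = 0; i < L; ++i) {
      double pi = p_spike(ro_dt, &Qs[i], L, A, p);
      lw += xk[i] ? std::log(pi) : std::log(1.0 - pi);
    }
    logw[s] = lw;
    if (lw > best) best = lw;
  }
  NumericVector out(nstates);
  double tot = 0;
  for (int s = 0; s < nstates; ++s) { out[s] = std::exp(logw[s] - best); tot += out[s]; }
  for (int s = 0; s < nstates; ++s) out[s] /= tot;
  return out;
}
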