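#include <Rcpp.h>
using namespace Rcpp;

// Structured variational inference for the trajectory posterior of a
// discrete-state active-inference model.  The joint density is
//
//   P(s, o) = prod_f [ D_f(s_f1) prod_{tau>1} B_f(s_{f,tau} | s_{f,tau-1}) ]
//             * prod_{observed tau} P(o_tau | s_tau)
//
// The variational posterior factorizes over hidden factors but keeps each
// factor's temporal chain intact: q(s) = prod_f q_f(s_{f,1:T}).  Each
// coordinate update solves one factor's chain exactly (forward-backward)
// given the other factors' marginals, so the structured free energy is
// non-increasing across sweeps.  This avoids the overconfidence that
// fully-factorized (per-time-point) mean field exhibits on
// near-deterministic chains, where forward and backward messages reinforce
// each other.
//
// For the structured posterior the free energy has the closed form
//
//   F = (Nf - 1) * sum_obs E_q[ ln P(o_tau | s_tau) ]  -  sum_f ln Z_f
//
// where Z_f is the partition function of factor f's evidence-weighted
// chain.  Observed-epoch likelihoods enter as flattened joint arrays over
// the state space (summed over modalities, evaluated at the observed
// outcome), column-major with factor 1 varying fastest.

// contraction of flat joint array X (dims d) with marginals q[g][, tau] for
// all g != f; returns vector over levels of factor f
static void contract_except(const NumericVector& X,
                            const IntegerVector& dims,
                            const std::vector<NumericMatrix>& qs,
                            int tau, int f,
                            std::vector<double>& out) {
  const int nf = dims.size();
  const int n = X.size();
  std::fill(out.begin(), out.end(), 0.0);
  std::vector<int> idx(nf, 0);
  for (int cell = 0; cell < n; ++cell) {
    double w = 1.0;
    for (int g = 0; g < nf; ++g) {
      if (g != f) w *= qs[g](idx[g], tau);
    }
    out[idx[f]] += X[cell] * w;
    for (int g = 0; g < nf; ++g) {
      if (++idx[g] < dims[g]) break;
      idx[g] = 0;
    }
  }
}

// full contraction of X with all factors' marginals at time tau
static double contract_all(const NumericVector& X,
                           const IntegerVector& dims,
                           const std::vector<NumericMatrix>& qs,
                           int tau) {
  const int nf = dims.size();
  const int n = X.size();
  double acc = 0.0;
  std::vector<int> idx(nf, 0);
  for (int cell = 0; cell < n; ++cell) {
    double w = 1.0;
    for (int g = 0; g < nf; ++g) w *= qs[g](idx[g], tau);
    acc += X[cell] * w;
    for (int g = 0; g < nf; ++g) {
      if (++idx[g] < dims[g]) break;
      idx[g] = 0;
    }
  }
  return acc;
}

// exact forward-backward solve of one factor's chain under the evidence
// messages Ev (levels x T, log scale); writes marginals into q and returns
// ln Z of the evidence-weighted chain
static double solve_chain(const NumericVector& lnD,
                          const List& lnB,       // T-1 matrices (log scale)
                          const std::vector<std::vector<double> >& Ev,
                          NumericMatrix& q) {
  const int d = q.nrow();
  const int T = q.ncol();
  std::vector<std::vector<double> > alpha(T, std::vector<double>(d));
  std::vector<std::vector<double> > beta(T, std::vector<double>(d, 1.0));
  double logZ = 0.0;

  // forward pass with per-step normalization
  double c = 0.0;
  for (int i = 0; i < d; ++i) {
    alpha[0][i] = std::exp(lnD[i] + Ev[0][i]);
    c += alpha[0][i];
  }
  logZ += std::log(c);
  for (int i = 0; i < d; ++i) alpha[0][i] /= c;
  for (int t = 1; t < T; ++t) {
    NumericMatrix Bm = lnB[t - 1];
    c = 0.0;
    for (int i = 0; i < d; ++i) {
      double acc = 0.0;
      for (int j = 0; j < d; ++j) acc += std::exp(Bm(i, j)) * alpha[t - 1][j];
      alpha[t][i] = acc * std::exp(Ev[t][i]);
      c += alpha[t][i];
    }
    logZ += std::log(c);
    for (int i = 0; i < d; ++i) alpha[t][i] /= c;
  }

  // backward pass (normalized for stability; constants cancel in q)
  for (int t = T - 2; t >= 0; --t) {
    NumericMatrix Bm = lnB[t];
    double bc = 0.0;
    for (int j = 0; j < d; ++j) {
      double acc = 0.0;
      for (int i = 0; i < d; ++i)
        acc += std::exp(Bm(i, j)) * std::exp(Ev[t + 1][i]) * beta[t + 1][i];
      beta[t][j] = acc;
      bc += acc;
    }
    if (bc > 0) for (int j = 0; j < d; ++j) beta[t][j] /= bc;
  }

  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int i = 0; i < d; ++i) {
      q(i, t) = alpha[t][i] * beta[t][i];
      s += q(i, t);
    }
    for (int i = 0; i < d; ++i) q(i, t) /= s;
  }
  return logZ;
}

// [[Rcpp::export]]
List cpp_infer_policy(List L, IntegerVector obs_tau, List lnB, List lnD,
                      IntegerVector dims, int T, int n_iter, double tol,
                      bool trace) {
  const int nf = dims.size();
  std::vector<NumericMatrix> qs(nf);
  for (int f = 0; f < nf; ++f) {
    NumericMatrix q(dims[f], T);
    std::fill(q.begin(), q.end(), 1.0 / dims[f]);
    qs[f] = q;
  }
  std::vector<double> logZ(nf, 0.0);
  std::vector<double> ev_dot(nf, 0.0);
  std::vector<double> F_iter;
  F_iter.reserve(n_iter);
  List sweeps(trace ? n_iter : 0);

  std::vector<double> msg;
  double F_prev = R_PosInf;
  int used = 0;

  for (int it = 0; it < n_iter; ++it) {
    for (int f = 0; f < nf; ++f) {
      const int d = dims[f];
      std::vector<std::vector<double> > Ev(T, std::vector<double>(d, 0.0));
      msg.assign(d, 0.0);
      for (int k = 0; k < obs_tau.size(); ++k) {
        NumericVector X = L[k];
        int tau = obs_tau[k] - 1;
        contract_except(X, dims, qs, tau, f, msg);
        for (int i = 0; i < d; ++i) Ev[tau][i] += msg[i];
      }
      NumericVector df = lnD[f];
      List Bf = lnB[f];
      logZ[f] = solve_chain(df, Bf, Ev, qs[f]);
      // E_{q_f}[ln q_f] - E_{q_f}[ln chain_f] = sum_tau q_f . Ev_f - ln Z_f
      // exactly, because q_f is the chain posterior for this evidence
      ev_dot[f] = 0.0;
      for (int t = 0; t < T; ++t)
        for (int i = 0; i < d; ++i) ev_dot[f] += qs[f](i, t) * Ev[t][i];
    }
    // structured free energy at the current posterior
    double F = 0.0;
    for (int f = 0; f < nf; ++f) F += ev_dot[f] - logZ[f];
    for (int k = 0; k < obs_tau.size(); ++k) {
      NumericVector X = L[k];
      F -= contract_all(X, dims, qs, obs_tau[k] - 1);
    }
    F_iter.push_back(F);
    if (trace) {
      List snap(nf);
      for (int f = 0; f < nf; ++f) snap[f] = clone(qs[f]);
      sweeps[it] = snap;
    }
    used = it + 1;
    if (it > 0 && (F_prev - F) < tol) break;
    F_prev = F;
  }

  List qs_out(nf);
  for (int f = 0; f < nf; ++f) qs_out[f] = qs[f];
  List out = List::create(
    _["qs"] = qs_out,
    _["F"] = F_iter[used - 1],
    _["F_iter"] = NumericVector(F_iter.begin(), F_iter.begin() + used));
  if (trace) {
    List tr(used);
    for (int i = 0; i < used; ++i) tr[i] = sweeps[i];
    out["trace"] = tr;
  }
  return out;
}

// generic tensor contraction helper: contract flat joint array X with the
// supplied marginals; if keep > 0 (1-based factor index) return the vector
// over that factor's levels, else the scalar full contraction
// [[Rcpp::export]]
NumericVector cpp_contract(NumericVector X, IntegerVector dims, List q,
                           int keep) {
  const int nf = dims.size();
  std::vector<NumericMatrix> qs(nf);
  for (int f = 0; f < nf; ++f) {
    NumericVector qi = q[f];
    NumericMatrix m(qi.size(), 1);
    for (int i = 0; i < qi.size(); ++i) m(i, 0) = qi[i];
    qs[f] = m;
  }
  if (keep > 0) {
    std::vector<double> out(dims[keep - 1], 0.0);
    contract_except(X, dims, qs, 0, keep - 1, out);
    return NumericVector(out.begin(), out.end());
  }
  return NumericVector::create(contract_all(X, dims, qs, 0));
}
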