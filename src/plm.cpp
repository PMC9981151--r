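#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Weighted negative log-pseudo-likelihood and gradient for one site of the
// asymmetric PLM. Parameter layout (length q + (L-1)*q*q):
//   par[0..q-1]                    h_i(a)
//   then for each j != i (ascending j), a q x q block stored column-major
//   with entry (a, b) = J_ij(a at site i, b at site j) at offset
//   q + jj*q*q + b*q + a, jj = 0-based index of j among the L-1 neighbours.
// codes is 1-based (n x L); site is 1-based. Objective:
//   sum_s w_s * [logsumexp_a(logit_a) - logit_{x_si}]
//   + lambda_h * ||h||^2 + lambda_J * ||J||^2
// [[Rcpp::export]]
List cpp_plm_site(const IntegerMatrix& codes, int site,
                  const NumericVector& w, double lambda_h, double lambda_J,
                  const NumericVector& par) {
  const int n = codes.nrow(), L = codes.ncol();
  const int i = site - 1;
  const int q = static_cast<int>(
      std::lround((std::sqrt(1.0 + 4.0 * (L - 1) * par.size()) - 1.0) /
                  (2.0 * (L - 1))));
  if (q + (L - 1) * q * q != (int)par.size())
    stop("parameter vector length inconsistent with alignment dimensions");

  NumericVector grad(par.size());
  std::vector<double> logit(q), p(q);
  double value = 0.0;

  for (int s = 0; s < n; ++s) {
    const double ws = w[s];
    for (int a = 0; a < q; ++a) logit[a] = par[a];
    int jj = 0;
    for (int j = 0; j < L; ++j) {
      if (j == i) continue;
      const int xj = codes(s, j) - 1;
      const int off = q + jj * q * q + xj * q;
      for (int a = 0; a < q; ++a) logit[a] += par[off + a];
      ++jj;
    }
    double mx = logit[0];
    for (int a = 1; a < q; ++a) if (logit[a] > mx) mx = logit[a];
    double Zs = 0.0;
    for (int a = 0; a < q; ++a) { p[a] = std::exp(logit[a] - mx); Zs += p[a]; }
    const int xi = codes(s, i) - 1;
    value += ws * (std::log(Zs) + mx - logit[xi]);
    for (int a = 0; a < q; ++a) p[a] = ws * p[a] / Zs;
    p[xi] -= ws;
    // p now holds w_s * (P(a|rest) - delta(a, x_si)) = d nll / d logit_a
    for (int a = 0; a < q; ++a) grad[a] += p[a];
    jj = 0;
    for (int j = 0; j < L; ++j) {
      if (j == i) continue;
      const int xj = codes(s, j) - 1;
      const int off = q + jj * q * q + xj * q;
      for (int a = 0; a < q; ++a) grad[off + a] += p[a];
      ++jj;
    }
  }

  double reg = 0.0;
  for (int k = 0; k < q; ++k) {
    reg += lambda_h * par[k] * par[k];
    grad[k] += 2.0 * lambda_h * par[k];
  }
  for (int k = q; k < (int)par.size(); ++k) {
    reg += lambda_J * par[k] * par[k];
    grad[k] += 2.0 * lambda_J * par[k];
  }
  return List::create(_["value"] = value + reg, _["grad"] = grad);
}

// Identity-based sequence weights: w_s = 1 / #{t : id(s,t) >= thr}.
// Identity counts matching coded states over all L columns (gap == gap is a
// match); with non_gap_only, only columns where both sequences are non-gap
// enter numerator and denominator (identity 0 when no such column).
// [[Rcpp::export]]
NumericVector cpp_pair_weights(const IntegerMatrix& codes, double thr,
                               bool non_gap_only) {
  const int n = codes.nrow(), L = codes.ncol();
  std::vector<int> nb(n, 1); // self included
  for (int s = 0; s < n - 1; ++s) {
    for (int t = s + 1; t < n; ++t) {
      int match = 0, denom = 0;
      for (int c = 0; c < L; ++c) {
        const int a = codes(s, c), b = codes(t, c);
        if (non_gap_only) {
          if (a == 1 || b == 1) continue;
          ++denom;
          if (a == b) ++match;
        } else {
          ++denom;
          if (a == b) ++match;
        }
      }
      const double id = denom > 0 ? (double)match / denom : 0.0;
      if (id >= thr) { ++nb[s]; ++nb[t]; }
    }
  }
  NumericVector w(n);
  for (int s = 0; s < n; ++s) w[s] = 1.0 / nb[s];
  return w;
}

// Single-chain Gibbs sampler for a sparse-coupling Potts model.
// h: L x q fields; edges: E x 2 (1-based column pairs i < j);
// Jblocks: E * q * q, block e stored column-major with entry (a, b) =
// J(state a at edges[e,1], state b at edges[e,2]).
// Returns n_samples x L matrix of 1-based states; uses R's RNG.
// [[Rcpp::export]]
IntegerMatrix cpp_gibbs_potts(const NumericMatrix& h,
                              const IntegerMatrix& edges,
                              const NumericVector& Jblocks,
                              int n_samples, int burn_in, int thinning) {
  const int L = h.nrow(), q = h.ncol(), E = edges.nrow();
  // adjacency: for each site, list of (edge index, is_first_endpoint)
  std::vector<std::vector<std::pair<int, bool> > > adj(L);
  for (int e = 0; e < E; ++e) {
    adj[edges(e, 0) - 1].push_back(std::make_pair(e, true));
    adj[edges(e, 1) - 1].push_back(std::make_pair(e, false));
  }
  std::vector<int> x(L);
  for (int i = 0; i < L; ++i)
    x[i] = (int)(unif_rand() * q); // 0-based state
  IntegerMatrix out(n_samples, q > 0 ? L : 0);
  std::vector<double> e_a(q);
  const int total = burn_in + n_samples * thinning;
  int kept = 0;
  for (int sweep = 1; sweep <= total && kept < n_samples; ++sweep) {
    for (int i = 0; i < L; ++i) {
      for (int a = 0; a < q; ++a) e_a[a] = h(i, a);
      for (size_t k = 0; k < adj[i].size(); ++k) {
        const int e = adj[i][k].first;
        if (adj[i][k].second) {
          const int xj = x[edges(e, 1) - 1];
          const double* blk = &Jblocks[e * q * q];
          for (int a = 0; a < q; ++a) e_a[a] += blk[xj * q + a];
        } else {
          const int xj = x[edges(e, 0) - 1];
          const double* blk = &Jblocks[e * q * q];
          for (int a = 0; a < q; ++a) e_a[a] += blk[a * q + xj];
        }
      }
      double mx = e_a[0];
      for (int a = 1; a < q; ++a) if (e_a[a] > mx) mx = e_a[a];
      double Z = 0.0;
      for (int a = 0; a < q; ++a) { e_a[a] = std::exp(e_a[a] - mx); Z += e_a[a]; }
      double u = unif_rand() * Z, cum = 0.0;
      int pick = q - 1;
      for (int a = 0; a < q; ++a) {
        cum += e_a[a];
        if (u <= cum) { pick = a; break; }
      }
      x[i] = pick;
    }
    if (sweep > burn_in && (sweep - burn_in) % thinning == 0) {
      for (int i = 0; i < L; ++i) out(kept, i) = x[i] + 1;
      ++kept;
    }
  }
  return out;
}
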