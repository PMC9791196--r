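// EM E-step kernels for marginal maximum likelihood IRT calibration.
//
// Two latent-grid layouts are supported:
//  * joint_estep():   a single quadrature grid shared by all items (UIRT's
//    1-D grid, or the between-item MIRT tensor grid with Cholesky-
//    transformed nodes).  Each item's category probabilities are
//    pre-evaluated on the grid in R and passed in as G x K matrices.
//  * bifactor_estep(): the dimension-reduced bifactor grid.  Conditional on
//    the general factor the specific factors are independent, so the
//    6-D integral factors into a 1-D outer integral over theta0 times one
//    1-D inner integral per item group.  Grids are indexed g = q0*Qs + qs
//    (inner/specific index fastest).
//
// Both kernels return the marginal log-likelihood, optionally the expected
// category counts per item on the grid (the E-step sufficient statistics),
// posterior latent moments, and EAP scores.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List joint_estep(IntegerMatrix resp, List probs, NumericVector w,
                 NumericMatrix Theta, bool counts, bool scores,
                 bool moments) {
  const int N = resp.nrow(), M = resp.ncol();
  const int G = w.size(), d = Theta.ncol();
  const int *rp = resp.begin();          // column-major: rp[i + j*N]
  const double *wp = w.begin();

  // per item, per category column pointers into the probability matrices
  std::vector<NumericMatrix> P(M);
  std::vector<int> K(M);
  for (int j = 0; j < M; ++j) {
    P[j] = as<NumericMatrix>(probs[j]);
    K[j] = P[j].ncol();
  }
  std::vector<const double*> thcol(d);
  for (int k = 0; k < d; ++k) thcol[k] = &Theta(0, k);

  List r(M);
  std::vector<double*> rptr(M, (double*)0);
  if (counts)
    for (int j = 0; j < M; ++j) {
      NumericMatrix rj(G, K[j]);
      r[j] = rj;
      rptr[j] = rj.begin();
    }

  NumericMatrix eap, psd;
  double *ep = 0, *pp = 0;
  if (scores) {
    eap = NumericMatrix(N, d); psd = NumericMatrix(N, d);
    ep = eap.begin(); pp = psd.begin();
  }
  NumericMatrix S(d, d);
  NumericVector pll(N);
  std::vector<double> L(G), post(G), postsum(G, 0.0);
  double loglik = 0.0;

  for (int i = 0; i < N; ++i) {
    int nobs = 0;
    std::fill(L.begin(), L.end(), 1.0);
    for (int j = 0; j < M; ++j) {
      const int x = rp[i + j * N];
      if (x == NA_INTEGER) continue;
      ++nobs;
      const double *pj = P[j].begin() + (size_t)x * G;
      for (int g = 0; g < G; ++g) L[g] *= pj[g];
    }
    if (nobs == 0) {            // no data: posterior = prior
      pll[i] = 0.0;
      if (scores)
        for (int k = 0; k < d; ++k) { ep[i + k * N] = 0.0;
                                      pp[i + k * N] = 1.0; }
      continue;
    }
    double lsum = 0.0;
    for (int g = 0; g < G; ++g) lsum += wp[g] * L[g];
    pll[i] = std::log(lsum);
    loglik += pll[i];
    for (int g = 0; g < G; ++g) post[g] = wp[g] * L[g] / lsum;
    if (moments)
      for (int g = 0; g < G; ++g) postsum[g] += post[g];

    if (counts) {
      for (int j = 0; j < M; ++j) {
        const int x = rp[i + j * N];
        if (x == NA_INTEGER) continue;
        double *col = rptr[j] + (size_t)x * G;
        for (int g = 0; g < G; ++g) col[g] += post[g];
      }
    }
    if (scores) {
      for (int k = 0; k < d; ++k) {
        const double *t = thcol[k];
        double m1 = 0.0, m2 = 0.0;
        for (int g = 0; g < G; ++g) {
          m1 += post[g] * t[g];
          m2 += post[g] * t[g] * t[g];
        }
        ep[i + k * N] = m1;
        double v = m2 - m1 * m1;
        pp[i + k * N] = v > 0 ? std::sqrt(v) : 0.0;
      }
    }
  }
  if (moments) {
    // S = Theta' diag(sum_i post_i) Theta (grid shared across persons)
    for (int a = 0; a < d; ++a)
      for (int b = a; b < d; ++b) {
        double s = 0.0;
        const double *ta = thcol[a], *tb = thcol[b];
        for (int g = 0; g < G; ++g) s += postsum[g] * ta[g] * tb[g];
        S(a, b) = s;
        S(b, a) = s;
      }
  }

  return List::create(_["loglik"] = loglik, _["pll"] = pll, _["r"] = r,
                      _["S"] = S, _["eap"] = eap, _["psd"] = psd);
}

// [[Rcpp::export]]
List bifactor_estep(IntegerMatrix resp, List probs, IntegerVector group,
                    int n_domains, NumericVector w0, NumericVector ws,
                    NumericVector x0, NumericVector xs, bool counts,
                    bool scores) {
  const int N = resp.nrow(), M = resp.ncol();
  const int Q0 = w0.size(), Qs = ws.size(), G = Q0 * Qs;
  const int D = n_domains;

  std::vector<NumericMatrix> P(M);
  std::vector<int> K(M);
  for (int j = 0; j < M; ++j) {
    P[j] = as<NumericMatrix>(probs[j]);
    K[j] = P[j].ncol();
  }
  // items of each group
  std::vector< std::vector<int> > gitems(D);
  for (int j = 0; j < M; ++j) gitems[group[j]].push_back(j);

  List r(M);
  if (counts)
    for (int j = 0; j < M; ++j) r[j] = NumericMatrix(G, K[j]);

  NumericMatrix eap, psd;
  if (scores) {
    eap = NumericMatrix(N, D + 1);
    psd = NumericMatrix(N, D + 1);
  }
  NumericVector pll(N);
  double loglik = 0.0;

  std::vector<double> A(D * G), Gv(D * Q0), H(Q0), post(G), base(Q0);
  std::vector<bool> obs(D);
  std::vector<int> vobs;

  for (int i = 0; i < N; ++i) {
    std::fill(obs.begin(), obs.end(), false);
    int nobs = 0;
    for (int j = 0; j < M; ++j) {
      int x = resp(i, j);
      if (x == NA_INTEGER) continue;
      ++nobs;
      const int v = group[j];
      double *Av = &A[v * G];
      if (!obs[v]) { obs[v] = true; std::fill(Av, Av + G, 1.0); }
      const double *pj = &P[j](0, x);
      for (int g = 0; g < G; ++g) Av[g] *= pj[g];
    }
    if (nobs == 0) {
      pll[i] = 0.0;
      if (scores)
        for (int k = 0; k <= D; ++k) { eap(i, k) = 0.0; psd(i, k) = 1.0; }
      continue;
    }
    vobs.clear();
    for (int v = 0; v < D; ++v) if (obs[v]) vobs.push_back(v);
    const int m = (int)vobs.size();

    // inner integrals: Gv(q0) = sum_qs ws * A_v(q0, qs)
    for (int t = 0; t < m; ++t) {
      const int v = vobs[t];
      const double *Av = &A[v * G];
      double *gv = &Gv[v * Q0];
      for (int q0 = 0; q0 < Q0; ++q0) {
        double s = 0.0;
        const double *a = Av + q0 * Qs;
        for (int qs = 0; qs < Qs; ++qs) s += ws[qs] * a[qs];
        gv[q0] = s;
      }
    }
    // outer integrand H(q0) and marginal likelihood
    for (int q0 = 0; q0 < Q0; ++q0) {
      double h = 1.0;
      for (int t = 0; t < m; ++t) h *= Gv[vobs[t] * Q0 + q0];
      H[q0] = h;
    }
    double lsum = 0.0;
    for (int q0 = 0; q0 < Q0; ++q0) lsum += w0[q0] * H[q0];
    pll[i] = std::log(lsum);
    loglik += pll[i];

    if (scores) {
      double m1 = 0.0, m2 = 0.0;
      for (int q0 = 0; q0 < Q0; ++q0) {
        const double pg = w0[q0] * H[q0] / lsum;
        m1 += pg * x0[q0];
        m2 += pg * x0[q0] * x0[q0];
      }
      eap(i, 0) = m1;
      double v0 = m2 - m1 * m1;
      psd(i, 0) = v0 > 0 ? std::sqrt(v0) : 0.0;
      for (int k = 1; k <= D; ++k) { eap(i, k) = 0.0; psd(i, k) = 1.0; }
    }
    if (!counts && !scores) continue;

    // leave-one-out products over groups via prefix/suffix (avoids division
    // by possibly tiny group likelihoods)
    std::vector<double> pre((m + 1) * Q0), suf((m + 1) * Q0);
    for (int q0 = 0; q0 < Q0; ++q0) { pre[q0] = 1.0; suf[m * Q0 + q0] = 1.0; }
    for (int t = 0; t < m; ++t)
      for (int q0 = 0; q0 < Q0; ++q0)
        pre[(t + 1) * Q0 + q0] =
          pre[t * Q0 + q0] * Gv[vobs[t] * Q0 + q0];
    for (int t = m - 1; t >= 0; --t)
      for (int q0 = 0; q0 < Q0; ++q0)
        suf[t * Q0 + q0] =
          suf[(t + 1) * Q0 + q0] * Gv[vobs[t] * Q0 + q0];

    for (int t = 0; t < m; ++t) {
      const int v = vobs[t];
      const double *Av = &A[v * G];
      for (int q0 = 0; q0 < Q0; ++q0)
        base[q0] = w0[q0] * pre[t * Q0 + q0] * suf[(t + 1) * Q0 + q0] / lsum;
      for (int q0 = 0; q0 < Q0; ++q0) {
        const double b = base[q0];
        const double *a = Av + q0 * Qs;
        double *p = &post[q0 * Qs];
        for (int qs = 0; qs < Qs; ++qs) p[qs] = b * ws[qs] * a[qs];
      }
      if (counts) {
        for (size_t u = 0; u < gitems[v].size(); ++u) {
          const int j = gitems[v][u];
          int x = resp(i, j);
          if (x == NA_INTEGER) continue;
          NumericMatrix rj = r[j];
          double *col = &rj(0, x);
          for (int g = 0; g < G; ++g) col[g] += post[g];
        }
      }
      if (scores) {
        double m1 = 0.0, m2 = 0.0;
        for (int q0 = 0; q0 < Q0; ++q0) {
          const double *p = &post[q0 * Qs];
          for (int qs = 0; qs < Qs; ++qs) {
            m1 += p[qs] * xs[qs];
            m2 += p[qs] * xs[qs] * xs[qs];
          }
        }
        eap(i, v + 1) = m1;
        double vv = m2 - m1 * m1;
        psd(i, v + 1) = vv > 0 ? std::sqrt(vv) : 0.0;
      }
    }
  }

  return List::create(_["loglik"] = loglik, _["pll"] = pll, _["r"] = r,
                      _["eap"] = eap, _["psd"] = psd);
}
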