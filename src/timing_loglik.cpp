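#include <Rcpp.h>
using namespace Rcpp;

// Marginal likelihood machinery for the passenger-count timing model.
//
// Per sample the observed data are (N = passenger count, A_j/G_j driver
// indicators, t_max = patient age / division time). Latent: tumor age T
// (Gamma(alpha,beta) truncated to [t_min, t_max]), per-driver alteration
// time X_j (atom p_j at infinity + Gamma(alpha_j,beta_j)), exposure E
// (Exponential(rho)). N | T,X,E ~ Poisson(lam*T + sum_j delta_j*(T-X_j) + E).
//
// Numerical scheme (all deterministic):
//  * The integral over (X_j..., E) at fixed T is evaluated exactly as a
//    convolution over count allocations: N is a superposition of
//    independent Poisson components (baseline, one per altered mutator
//    driver, exposure), so each component's count distribution is
//    marginalised separately and the components combined by discrete
//    convolution. The exposure+baseline component has a closed-form
//    O(1)-per-count recursion (Poisson mixed over an exponential).
//  * The T integral uses Gauss-Legendre in the probability space of the
//    truncated prior (nodes at prior quantiles), so arbitrarily
//    concentrated tumor-age priors remain exactly resolved.
//  * Each alteration-time integral uses equal-mass quantile cells of the
//    driver's Gamma prior, evaluated at the cell-midpoint quantile and
//    clipped at t (the cell containing t contributes its partial mass).
//    This keeps the rule accurate for sharply peaked priors, which plain
//    node-based quadrature on (0, t] cannot resolve.
//
// Samples sharing the same t_max (ages are typically whole years) share
// the same T grid, so per-driver, per-node quantities are cached per
// unique t_max ("group") and reused across samples.

static const double DELTA_TOL = 1e-12;

// Poisson pmf vector p[0..n] for mean m. Multiplicative recurrence for
// moderate m; log-space recursion when exp(-m) would underflow (so large
// counts with large means keep their small but nonzero mass).
static void pois_vec(int n, double m, std::vector<double>& p) {
  if (m < 600.0) {
    double pk = std::exp(-m);
    p[0] = pk;
    for (int k = 1; k <= n; ++k) { pk *= m / k; p[k] = pk; }
  } else {
    double lp = -m;
    const double lm = std::log(m);
    p[0] = std::exp(lp);
    for (int k = 1; k <= n; ++k) {
      lp += lm - std::log((double)k);
      p[k] = std::exp(lp);
    }
  }
}

// ek[k] = P(N_base + N_exposure = k) for baseline mean m0 and exposure
// rate rho: ek[k] = ek[k-1]/(1+rho) + rho/(1+rho) * Pois(k; m0).
static void exposure_vec(int n, double m0, double rho,
                         std::vector<double>& pois_buf,
                         std::vector<double>& ek) {
  const double a = 1.0 / (1.0 + rho);
  const double b = rho * a;
  if (m0 <= 0.0) {
    ek[0] = b;
    for (int k = 1; k <= n; ++k) ek[k] = ek[k - 1] * a;
    return;
  }
  pois_vec(n, m0, pois_buf);
  ek[0] = b * pois_buf[0];
  for (int k = 1; k <= n; ++k) ek[k] = ek[k - 1] * a + b * pois_buf[k];
}

// res[k] = sum_{i=0..k} a[i] * b[k-i], vectors of length n+1
static void conv_trunc(const std::vector<double>& a,
                       const std::vector<double>& b,
                       int n, std::vector<double>& res) {
  for (int k = 0; k <= n; ++k) {
    double s = 0.0;
    for (int i = 0; i <= k; ++i) s += a[i] * b[k - i];
    res[k] = s;
  }
}

// [[Rcpp::export]]
List timing_loglik_cpp(IntegerVector N, NumericVector tmax,
                       IntegerMatrix A, IntegerMatrix G,
                       double alpha, double beta, double rho,
                       double lam, double tmin,
                       NumericVector alpha_j, NumericVector beta_j,
                       NumericVector delta_j, NumericVector p_j,
                       NumericVector tnodes, NumericVector twts,
                       int n_xcells,
                       NumericVector w, bool posteriors) {
  const int ns = N.size();
  const int J = alpha_j.size();
  const int KT = tnodes.size();
  const int KD = n_xcells;

  NumericVector loglik(ns);
  NumericVector postT(ns, NA_REAL);
  NumericMatrix postX(ns, J);
  std::fill(postX.begin(), postX.end(), NA_REAL);

  // Per-driver equal-mass cells of the Gamma part of the X prior: cell c
  // covers prior mass ((c-1)/KD, c/KD]; each cell is represented by its
  // conditional mean, computed from the shape+1 partial-moment identity
  // E[X; X <= x] = (alpha_j/beta_j) * F_{alpha_j + 1}(x). Cell-mean
  // evaluation stays second-order accurate in prior mass even where the
  // quantile function is singular (v -> 0) or the prior is a spike.
  std::vector< std::vector<double> > xb(J, std::vector<double>(KD + 1));
  std::vector< std::vector<double> > Fa1b(J, std::vector<double>(KD + 1));
  std::vector< std::vector<double> > xmean(J, std::vector<double>(KD));
  for (int j = 0; j < J; ++j) {
    const double mj = alpha_j[j] / beta_j[j];
    xb[j][0] = 0.0; Fa1b[j][0] = 0.0;
    xb[j][KD] = R_PosInf; Fa1b[j][KD] = 1.0;
    for (int c = 1; c < KD; ++c) {
      xb[j][c] = R::qgamma((double)c / KD, alpha_j[j], 1.0 / beta_j[j], 1, 0);
      Fa1b[j][c] = R::pgamma(xb[j][c], alpha_j[j] + 1.0, 1.0 / beta_j[j], 1, 0);
    }
    for (int c = 0; c < KD; ++c)
      xmean[j][c] = mj * (Fa1b[j][c + 1] - Fa1b[j][c]) * KD;
  }

  const double plo = R::pgamma(tmin, alpha, 1.0 / beta, 1, 0);

  // ---- group samples by identical t_max ----------------------------------
  std::vector<double> gt;
  std::vector<int> grp(ns, -1);
  std::vector<int> gnmax;
  for (int i = 0; i < ns; ++i) {
    int g = -1;
    for (size_t u = 0; u < gt.size(); ++u)
      if (gt[u] == tmax[i]) { g = (int)u; break; }
    if (g < 0) { gt.push_back(tmax[i]); gnmax.push_back(0); g = (int)gt.size() - 1; }
    grp[i] = g;
    if (N[i] > gnmax[g]) gnmax[g] = N[i];
  }
  const int NG = (int)gt.size();

  double total = 0.0;
  bool any_nonfinite = false;

  // group caches
  std::vector<double> tg(KT);
  std::vector< std::vector<double> > Fj(KT, std::vector<double>(J));
  std::vector< std::vector<double> > Frep(KT, std::vector<double>(J));
  std::vector< std::vector< std::vector<double> > > q, qx;
  std::vector< std::vector<double> > ek0(KT);

  for (int g = 0; g < NG; ++g) {
    const double tmx = gt[g];
    const int nmax = gnmax[g];
    const bool g_ok = (tmx > tmin);
    double phi = 0.0;
    if (g_ok) phi = R::pgamma(tmx, alpha, 1.0 / beta, 1, 0);
    const bool g_valid = g_ok && (phi - plo) > 0.0;

    if (g_valid) {
      q.assign(KT, std::vector< std::vector<double> >(J));
      if (posteriors) qx.assign(KT, std::vector< std::vector<double> >(J));
      std::vector<double> pois_buf(nmax + 1);
      for (int kt = 0; kt < KT; ++kt) {
        // T node at the prior quantile of the truncated range
        const double v = plo + tnodes[kt] * (phi - plo);
        tg[kt] = R::qgamma(v, alpha, 1.0 / beta, 1, 0);
        const double t = tg[kt];
        ek0[kt].assign(nmax + 1, 0.0);
        exposure_vec(nmax, lam * t, rho, pois_buf, ek0[kt]);
        for (int j = 0; j < J; ++j) {
          Fj[kt][j] = R::pgamma(t, alpha_j[j], 1.0 / beta_j[j], 1, 0);
          // partial first moment, needed for quantile-cell means (mutator
          // drivers) and for posterior alteration times
          if (posteriors || delta_j[j] > DELTA_TOL) {
            Frep[kt][j] = (alpha_j[j] / beta_j[j]) *
              R::pgamma(t, alpha_j[j] + 1.0, 1.0 / beta_j[j], 1, 0);
          }
          if (delta_j[j] > DELTA_TOL) {
            std::vector<double>& qv = q[kt][j];
            qv.assign(nmax + 1, 0.0);
            if (posteriors) qx[kt][j].assign(nmax + 1, 0.0);
            const double Ft = Fj[kt][j];
            for (int c = 0; c < KD; ++c) {
              const double v_lo = (double)c / KD;
              if (v_lo >= Ft) break;
              const double v_hi = (c + 1.0) / KD;
              const bool partial = (v_hi > Ft) || (xb[j][c + 1] > t);
              const double mass =
                (1.0 - p_j[j]) * ((v_hi < Ft ? v_hi : Ft) - v_lo);
              if (!(mass > 0.0)) continue;
              // conditional mean of X within (the retained part of) the cell
              double x;
              if (!partial) {
                x = xmean[j][c];
              } else {
                // Frep = (alpha/beta) * F_{alpha+1}(t) = E[X; X <= t]
                x = (Frep[kt][j] - (alpha_j[j] / beta_j[j]) * Fa1b[j][c]) /
                  (Ft - v_lo);
                if (x > t) x = t;
                if (x < xb[j][c]) x = xb[j][c];
              }
              const double rate = delta_j[j] * (t - x);
              if (rate < 600.0) {
                double pk = std::exp(-rate);
                for (int k = 0; k <= nmax; ++k) {
                  if (k > 0) pk *= rate / k;
                  qv[k] += mass * pk;
                  if (posteriors) qx[kt][j][k] += mass * x * pk;
                }
              } else {
                double lp = -rate, pk;
                const double lr = std::log(rate);
                for (int k = 0; k <= nmax; ++k) {
                  if (k > 0) lp += lr - std::log((double)k);
                  pk = std::exp(lp);
                  qv[k] += mass * pk;
                  if (posteriors) qx[kt][j][k] += mass * x * pk;
                }
              }
            }
          }
        }
      }
    }

    // ---- samples of this group, collapsed by (A, G) pattern ------------
    // Samples sharing the same t_max and the same indicator pattern have
    // identical integrands except for the observed count, so the whole
    // count vector is accumulated once per pattern and read off per
    // sample.
    std::vector<int> gidx;
    for (int i = 0; i < ns; ++i) if (grp[i] == g) gidx.push_back(i);
    if (!g_ok) {
      for (size_t u = 0; u < gidx.size(); ++u) loglik[gidx[u]] = NA_REAL;
      any_nonfinite = true;
      continue;
    }
    if (!g_valid) {
      for (size_t u = 0; u < gidx.size(); ++u) loglik[gidx[u]] = R_NegInf;
      any_nonfinite = true;
      continue;
    }

    std::vector<int> pat_rep;            // representative sample per pattern
    std::vector< std::vector<int> > pat_members;
    for (size_t u = 0; u < gidx.size(); ++u) {
      const int i = gidx[u];
      int p = -1;
      for (size_t v = 0; v < pat_rep.size(); ++v) {
        const int rp = pat_rep[v];
        bool same = true;
        for (int j = 0; j < J; ++j)
          if (A(i, j) != A(rp, j) || G(i, j) != G(rp, j)) { same = false; break; }
        if (same) { p = (int)v; break; }
      }
      if (p < 0) {
        pat_rep.push_back(i);
        pat_members.push_back(std::vector<int>());
        p = (int)pat_rep.size() - 1;
      }
      pat_members[p].push_back(i);
    }

    for (size_t pp = 0; pp < pat_rep.size(); ++pp) {
      const int rp = pat_rep[pp];
      const std::vector<int>& members = pat_members[pp];
      int n = 0;
      for (size_t u = 0; u < members.size(); ++u)
        if (N[members[u]] > n) n = N[members[u]];

      std::vector<int> jj_vec, jj_sca;
      double delta_germ = 0.0;
      for (int j = 0; j < J; ++j) {
        if (G(rp, j) == 1) { delta_germ += delta_j[j]; continue; }
        if (A(rp, j) == 1 && delta_j[j] > DELTA_TOL) jj_vec.push_back(j);
        else jj_sca.push_back(j);
      }
      const int d = (int)jj_vec.size();

      // distinct observed counts in this pattern: when no posterior
      // summaries are requested, the likelihood is only needed at these
      // counts, so full convolutions collapse to a few dot products
      std::vector<int> ks;
      for (size_t u = 0; u < members.size(); ++u) {
        const int k = N[members[u]];
        if (std::find(ks.begin(), ks.end(), k) == ks.end()) ks.push_back(k);
      }

      std::vector<double> V(n + 1), tmp(n + 1), ekg;
      std::vector<double> pois_buf(n + 1);
      std::vector<double> Lw(n + 1, 0.0), Tw;
      std::vector< std::vector<double> > Xw;
      if (posteriors) {
        Tw.assign(n + 1, 0.0);
        Xw.assign(J, std::vector<double>(n + 1, 0.0));
      }

      for (int kt = 0; kt < KT; ++kt) {
        const double t = tg[kt];
        const double wt = twts[kt];  // GL weights in prior-CDF space sum to 1

        const std::vector<double>* ek = &ek0[kt];
        if (delta_germ > 0.0) {
          ekg.assign(n + 1, 0.0);
          exposure_vec(n, (lam + delta_germ) * t, rho, pois_buf, ekg);
          ek = &ekg;
        }

        double P = 1.0;
        for (size_t u = 0; u < jj_sca.size(); ++u) {
          const int j = jj_sca[u];
          P *= (A(rp, j) == 1) ? (1.0 - p_j[j]) * Fj[kt][j]
                               : p_j[j] + (1.0 - p_j[j]) * (1.0 - Fj[kt][j]);
        }
        const double wP = wt * P;

        if (!posteriors && d == 0) {
          for (size_t u = 0; u < ks.size(); ++u)
            Lw[ks[u]] += wP * (*ek)[ks[u]];
          continue;
        }
        if (!posteriors && d == 1) {
          const std::vector<double>& qv = q[kt][jj_vec[0]];
          for (size_t u = 0; u < ks.size(); ++u) {
            const int k = ks[u];
            double s = 0.0;
            for (int i2 = 0; i2 <= k; ++i2) s += (*ek)[i2] * qv[k - i2];
            Lw[k] += wP * s;
          }
          continue;
        }

        std::copy(ek->begin(), ek->begin() + n + 1, V.begin());
        for (int u = 0; u < d; ++u) {
          conv_trunc(V, q[kt][jj_vec[u]], n, tmp);
          V.swap(tmp);
        }

        for (int k = 0; k <= n; ++k) Lw[k] += wP * V[k];
        if (posteriors) {
          for (int k = 0; k <= n; ++k) Tw[k] += wP * t * V[k];
          for (size_t u = 0; u < jj_sca.size(); ++u) {
            const int j = jj_sca[u];
            if (A(rp, j) != 1) continue;
            const double sfac = (1.0 - p_j[j]) * Fj[kt][j];
            if (sfac > 0.0) {
              const double f = wt * (P / sfac) * (1.0 - p_j[j]) * Frep[kt][j];
              for (int k = 0; k <= n; ++k) Xw[j][k] += f * V[k];
            }
          }
          for (int u = 0; u < d; ++u) {
            std::copy(ek->begin(), ek->begin() + n + 1, V.begin());
            for (int v2 = 0; v2 < d; ++v2) {
              conv_trunc(V, (v2 == u) ? qx[kt][jj_vec[v2]] : q[kt][jj_vec[v2]],
                         n, tmp);
              V.swap(tmp);
            }
            for (int k = 0; k <= n; ++k) Xw[jj_vec[u]][k] += wP * V[k];
          }
        }
      }

      for (size_t u = 0; u < members.size(); ++u) {
        const int i = members[u];
        const double L = Lw[N[i]];
        if (!(L > 0.0) || !R_FINITE(L)) {
          loglik[i] = R_NegInf;
          any_nonfinite = true;
          continue;
        }
        loglik[i] = std::log(L);
        total += w[i] * loglik[i];
        if (posteriors) {
          postT[i] = Tw[N[i]] / L;
          for (int j = 0; j < J; ++j) {
            if (G(i, j) == 1) postX(i, j) = 0.0;
            else if (A(i, j) == 1) postX(i, j) = Xw[j][N[i]] / L;
          }
        }
      }
    }
  }

  return List::create(_["loglik"] = loglik,
                      _["total"] = any_nonfinite ? NA_REAL : total,
                      _["postT"] = postT,
                      _["postX"] = postX);
}
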