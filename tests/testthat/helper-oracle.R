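# Independent brute-force oracle for the per-sample marginal likelihood:
# a dense 3-D midpoint Riemann sum over (tumor age, alteration time of the
# single somatically altered driver, exposure). Kept free of the package's
# quadrature machinery so it can serve as an external check.
brute_marginal_lik <- function(n, a, g, s, params, K = 200) {
  d <- params$drivers
  tmin <- params$t_min
  tmax <- s / params$r
  jalt <- which(a == 1 & g == 0)
  stopifnot(length(jalt) == 1)
  j <- jalt

  tg <- tmin + (seq_len(K) - 0.5) / K * (tmax - tmin)
  dt <- (tmax - tmin) / K
  ZT <- pgamma(tmax, params$alpha, rate = params$beta) -
    pgamma(tmin, params$alpha, rate = params$beta)
  emax <- 40 / params$rho
  eg <- (seq_len(K) - 0.5) / K * emax
  de <- emax / K
  fe <- dexp(eg, rate = params$rho)

  tot <- 0
  for (ti in tg) {
    fT <- dgamma(ti, params$alpha, rate = params$beta) / ZT
    P <- 1
    for (k in seq_len(nrow(d))) {
      if (k == j) next
      if (g[k] == 1) next
      if (a[k] == 0) {
        P <- P * (d$p_j[k] + (1 - d$p_j[k]) *
                    pgamma(ti, d$alpha_j[k], rate = d$beta_j[k],
                           lower.tail = FALSE))
      } else {
        P <- P * (1 - d$p_j[k]) * pgamma(ti, d$alpha_j[k], rate = d$beta_j[k])
      }
    }
    m0 <- params$lam * ti + sum(d$delta_j[g == 1] * ti)
    xg <- (seq_len(K) - 0.5) / K * ti
    dx <- ti / K
    fx <- (1 - d$p_j[j]) * dgamma(xg, d$alpha_j[j], rate = d$beta_j[j])
    mu <- outer(m0 + d$delta_j[j] * (ti - xg), eg, "+")
    inner <- as.numeric(fx %*% dpois(n, mu) %*% fe) * dx * de
    tot <- tot + fT * P * inner * dt
  }
  tot
}

# One Richardson step over grid doubling removes the midpoint rule's
# leading O(K^-2) error term; both inputs remain plain Riemann sums.
brute_marginal_lik_rich <- function(n, a, g, s, params, K = 200) {
  L1 <- brute_marginal_lik(n, a, g, s, params, K)
  L2 <- brute_marginal_lik(n, a, g, s, params, 2 * K)
  (4 * L2 - L1) / 3
}

# 1-D quadrature oracle for the no-mutator model: with all delta = 0 the
# alteration-time integrals reduce to probability factors and the
# exposure integral has the closed geometric-mixture form, leaving a
# single integral over the tumor age.
exposure_kernel_r <- function(k, m0, rho) {
  exp(log(rho) - (k + 1) * log1p(rho) + rho * m0 +
        ppois(k, (1 + rho) * m0, log.p = TRUE))
}

oracle_lik_delta0 <- function(n, a, g, s, params) {
  d <- params$drivers
  tmin <- params$t_min
  tmax <- s / params$r
  ZT <- pgamma(tmax, params$alpha, rate = params$beta) -
    pgamma(tmin, params$alpha, rate = params$beta)
  f <- function(t) {
    out <- dgamma(t, params$alpha, rate = params$beta) / ZT *
      exposure_kernel_r(n, params$lam * t, params$rho)
    for (k in seq_len(nrow(d))) {
      if (g[k] == 1) next
      Fk <- pgamma(t, d$alpha_j[k], rate = d$beta_j[k])
      out <- out * if (a[k] == 1) (1 - d$p_j[k]) * Fk else
        d$p_j[k] + (1 - d$p_j[k]) * (1 - Fk)
    }
    out
  }
  stats::integrate(f, tmin, tmax, rel.tol = 1e-10)$value
}

oracle_post_t_delta0 <- function(n, a, g, s, params) {
  d <- params$drivers
  tmin <- params$t_min
  tmax <- s / params$r
  ZT <- pgamma(tmax, params$alpha, rate = params$beta) -
    pgamma(tmin, params$alpha, rate = params$beta)
  f <- function(t, wt = 1) {
    out <- t^wt * dgamma(t, params$alpha, rate = params$beta) / ZT *
      exposure_kernel_r(n, params$lam * t, params$rho)
    for (k in seq_len(nrow(d))) {
      if (g[k] == 1) next
      Fk <- pgamma(t, d$alpha_j[k], rate = d$beta_j[k])
      out <- out * if (a[k] == 1) (1 - d$p_j[k]) * Fk else
        d$p_j[k] + (1 - d$p_j[k]) * (1 - Fk)
    }
    out
  }
  num <- stats::integrate(function(t) f(t, 1), tmin, tmax, rel.tol = 1e-10)$value
  den <- stats::integrate(function(t) f(t, 0), tmin, tmax, rel.tol = 1e-10)$value
  num / den
}

# Small two-driver parameter set used across the model tests.
toy_params <- function(delta = c(0.02, 0), lam = 0.01) {
  model_params(
    alpha = 4, beta = 4 / 1100, rho = 1, lam = lam, r = 8 / 365, t_min = 50,
    drivers = tibble::tibble(
      driver = c("M1", "P1"), alpha_j = 2, beta_j = 2 / 400,
      delta_j = delta, p_j = 0.4
    )
  )
}

# Mean of Gamma(shape, rate) truncated to [lo, hi].
trunc_gamma_mean <- function(shape, rate, lo, hi) {
  num <- pgamma(hi, shape + 1, rate = rate) - pgamma(lo, shape + 1, rate = rate)
  den <- pgamma(hi, shape, rate = rate) - pgamma(lo, shape, rate = rate)
  (shape / rate) * num / den
}
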