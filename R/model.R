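#' Poisson rate of passenger alterations for a given latent state
#'
#' The expected passenger count for a lineage of age `t` cell divisions:
#' `lam * t + sum(delta * (t - x)) + e`, where the sum runs over the altered
#' drivers, `x` are their alteration times (0 for germline events) and `e`
#' is the exposure term. Alteration of a mutator driver at time `x` adds
#' `delta` to the per-division rate for the remaining `t - x` divisions.
#'
#' @param t Tumor lineage age in cell divisions.
#' @param x Numeric vector of alteration times (cell divisions) of the
#'   altered drivers; may be empty.
#' @param delta Numeric vector of rate increases, same length as `x`.
#' @param lam Baseline alteration rate per cell division.
#' @param e Exposure term (expected extra alterations), default 0.
#' @return The nonnegative Poisson mean.
#' @examples
#' poisson_rate(1000, x = 400, delta = 0.005, lam = 0.01, e = 2) # 15
#' @export
poisson_rate <- function(t, x = numeric(), delta = numeric(), lam, e = 0) {
  stopifnot(length(x) == length(delta), t >= 0, e >= 0, all(delta >= 0))
  if (any(x > t)) {
    stop("alteration time x exceeds lineage age t for an altered driver")
  }
  lam * t + sum(delta * (t - x)) + e
}

#' Prior density of the tumor lineage age
#'
#' Gamma(`alpha`, `beta`) density renormalized to the interval
#' `[t_min, t_max]`; zero outside. `t_max` is the patient age divided by the
#' cell division time.
#'
#' @param t Evaluation points (cell divisions).
#' @param alpha,beta Gamma shape and rate.
#' @param t_min,t_max Truncation bounds, `t_max > t_min`.
#' @return Density values.
#' @export
prior_t_density <- function(t, alpha, beta, t_min, t_max) {
  if (!(t_max > t_min)) {
    stop("t_max <= t_min: patient too young for the lower age bound")
  }
  z <- pgamma(t_max, alpha, rate = beta) - pgamma(t_min, alpha, rate = beta)
  if (z <= 0) stop("truncated T prior has zero mass on [t_min, t_max]")
  ifelse(t >= t_min & t <= t_max, dgamma(t, alpha, rate = beta) / z, 0)
}

#' Alteration-time prior of a driver
#'
#' The alteration time `X` of driver `j` is infinite (the driver never
#' alters in the lineage) with probability `p_j`, and otherwise follows a
#' Gamma(`alpha_j`, `beta_j`) distribution on the positive axis.
#' `prior_x_density()` is the continuous part (carrying weight `1 - p_j`);
#' `prior_x_tail()` is `P(X > t)` including the atom at infinity, the factor
#' an unaltered driver contributes to the likelihood.
#'
#' @param x,t Evaluation points (cell divisions).
#' @param alpha_j,beta_j Gamma shape and rate of the finite part.
#' @param p_j Probability that the driver never alters.
#' @return Density values (`prior_x_density`) or tail probabilities
#'   (`prior_x_tail`).
#' @export
prior_x_density <- function(x, alpha_j, beta_j, p_j) {
  (1 - p_j) * dgamma(x, alpha_j, rate = beta_j)
}

#' @rdname prior_x_density
#' @export
prior_x_tail <- function(t, alpha_j, beta_j, p_j) {
  p_j + (1 - p_j) * pgamma(t, alpha_j, rate = beta_j, lower.tail = FALSE)
}

#' Prior density of the exposure term
#'
#' Exponential(`rho`) density on `e >= 0`. The exposure term absorbs extra
#' passenger alterations from unmodelled mutagen exposure.
#'
#' @param e Evaluation points (expected extra alterations).
#' @param rho Exponential rate.
#' @return Density values.
#' @export
prior_e_density <- function(e, rho) {
  stopifnot(rho > 0)
  dexp(e, rate = rho)
}

# Internal: C++ likelihood pass from a plain parameter list (no tibbles;
# used in optimizer hot loops). pv: alpha, beta, rho, lam, t_min,
# alpha_j, beta_j, delta_j, p_j aligned with m$drivers.
ll_eval_raw <- function(m, pv, quad, weights = NULL, posteriors = FALSE) {
  w <- if (is.null(weights)) rep(1, length(m$N)) else weights
  timing_loglik_cpp(
    N = m$N, tmax = m$S / pv$r, A = m$A, G = m$G,
    alpha = pv$alpha, beta = pv$beta, rho = pv$rho,
    lam = pv$lam, tmin = pv$t_min,
    alpha_j = pv$alpha_j, beta_j = pv$beta_j,
    delta_j = pv$delta_j, p_j = pv$p_j,
    tnodes = quad$t_nodes, twts = quad$t_wts,
    n_xcells = quad$n_x,
    w = w, posteriors = posteriors
  )
}

# Internal: one C++ likelihood pass over a cohort's matrix view.
# Returns list(loglik, total, postT, postX).
likelihood_pass <- function(m, params, quad, weights = NULL,
                            posteriors = FALSE) {
  d <- params$drivers
  if (!identical(sort(d$driver), sort(m$drivers))) {
    stop("drivers in params do not match drivers in cohort")
  }
  ord <- match(m$drivers, d$driver)
  pv <- list(
    alpha = params$alpha, beta = params$beta, rho = params$rho,
    lam = params$lam, r = params$r, t_min = params$t_min,
    alpha_j = d$alpha_j[ord], beta_j = d$beta_j[ord],
    delta_j = d$delta_j[ord], p_j = d$p_j[ord]
  )
  ll_eval_raw(m, pv, quad, weights, posteriors)
}

#' Marginal likelihood of one sample
#'
#' Integrates the Poisson observation density over the latent tumor age,
#' the alteration times of the altered drivers and the exposure term, on
#' the ranges consistent with the observed indicators: a germline driver
#' (`g = 1`) has alteration time fixed at 0; a somatically altered driver
#' (`a = 1, g = 0`) is integrated over `(0, t]` against the unnormalized
#' restriction of its prior; an unaltered driver contributes the scalar
#' mass `P(X > t)`. The result is the joint probability of observing the
#' count `n` and the alteration pattern `a` given `g` and the patient age.
#'
#' @param n Passenger alteration count.
#' @param a,g Integer vectors of altered/germline indicators, one entry per
#'   driver in `params$drivers` (same order).
#' @param s Patient age in years.
#' @param params A [model_params()] object.
#' @param quad A [quad_spec()] object.
#' @return A probability in `(0, 1]`.
#' @export
sample_marginal_likelihood <- function(n, a, g, s, params,
                                       quad = quad_spec()) {
  J <- nrow(params$drivers)
  stopifnot(length(a) == J, length(g) == J, n >= 0, s > 0)
  if (any(g > a)) stop("g = 1 requires a = 1 (germline implies altered)")
  if (s / params$r <= params$t_min) {
    stop("patient too young: S/r <= t_min")
  }
  m <- list(
    N = as.integer(n), S = as.numeric(s),
    A = matrix(as.integer(a), nrow = 1),
    G = matrix(as.integer(g), nrow = 1),
    drivers = params$drivers$driver
  )
  res <- likelihood_pass(m, params, quad)
  ll <- res$loglik[1]
  if (!is.finite(ll)) {
    stop(sprintf(
      "non-finite marginal likelihood (n=%d, s=%.3g); parameter values may be degenerate",
      n, s
    ))
  }
  exp(ll)
}

#' Cohort log-likelihood
#'
#' Sum of per-sample log marginal likelihoods (samples are independent).
#'
#' @param cohort A `mutclock_cohort` (see [as_cohort()]).
#' @param params A [model_params()] object.
#' @param quad A [quad_spec()] object.
#' @return The log-likelihood (a finite scalar); errors if any sample has
#'   zero or non-finite likelihood.
#' @export
cohort_loglik <- function(cohort, params, quad = quad_spec()) {
  stopifnot(nrow(cohort) > 0)
  m <- cohort_matrices(cohort)
  res <- likelihood_pass(m, params, quad)
  bad <- !is.finite(res$loglik)
  if (any(bad)) {
    stop("zero or undefined likelihood for sample(s): ",
         paste(m$sample[bad], collapse = ", "))
  }
  sum(res$loglik)
}
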