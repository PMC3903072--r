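# Parameter-vector packing for the optimizer.
#
# Free parameters (per driver j): log(alpha), log(beta), log(rho),
# log(alpha_j) with a lower bound at 0 (shape >= 1 keeps the Gamma density
# bounded at 0, which the alteration-time quadrature requires),
# log(beta_j), fold_j = delta_j / lam on the natural scale with a box at 0
# (so a no-mutator fit can land exactly on the boundary), and p_j in [0,1].

theta_template <- function(J, fix_delta_zero = FALSE) {
  nm <- c("log_alpha", "log_beta", "log_rho",
          paste0("log_alpha_j", seq_len(J)), paste0("log_beta_j", seq_len(J)),
          paste0("fold", seq_len(J)), paste0("p", seq_len(J)))
  lower <- c(rep(-20, 3), rep(0, J), rep(-20, J), rep(0, J), rep(0, J))
  upper <- c(rep(20, 3), rep(6, J), rep(6, J),
             rep(if (fix_delta_zero) 0 else 30, J), rep(1, J))
  list(names = nm, lower = lower, upper = upper, J = J)
}

theta_to_params <- function(theta, J, lam, r, t_min, driver_ids) {
  i <- 3
  model_params(
    alpha = exp(theta[1]), beta = exp(theta[2]), rho = exp(theta[3]),
    lam = lam, r = r, t_min = t_min,
    drivers = tibble::tibble(
      driver = driver_ids,
      alpha_j = exp(theta[i + seq_len(J)]),
      beta_j = exp(theta[i + J + seq_len(J)]),
      delta_j = lam * theta[i + 2 * J + seq_len(J)],
      p_j = theta[i + 3 * J + seq_len(J)]
    )
  )
}

params_to_theta <- function(params) {
  d <- params$drivers
  c(log(params$alpha), log(params$beta), log(params$rho),
    log(d$alpha_j), log(d$beta_j), d$delta_j / params$lam, d$p_j)
}

# Deterministic moment-style starting values.
default_starts <- function(m, lam, r, t_min, fix_delta_zero) {
  J <- length(m$drivers)
  tmax_med <- stats::median(m$S / r)
  T0 <- min(max(mean(m$N) / lam, 1.2 * t_min), 0.9 * tmax_med)
  carrier <- colMeans(m$A)
  p0 <- pmin(pmax(1 - carrier, 0.05), 0.95)
  base <- c(log(2), log(2 / T0), log(1),
            rep(log(1.5), J), rep(log(1.5 / (T0 / 2)), J),
            rep(0, J), p0)
  if (fix_delta_zero) return(list(base))
  alt <- base
  alt[3 + 2 * J + seq_len(J)] <- 1   # all drivers start at delta = lam
  list(base, alt)
}

#' Fit the timing model by maximum marginal likelihood
#'
#' Estimates the hyperparameters (tumor-age prior, per-driver
#' alteration-time priors and never-alters probabilities, per-driver rate
#' increases, exposure rate) by maximizing the cohort marginal likelihood
#' with a bound-constrained quasi-Newton optimizer (PORT/`nlminb`) over a
#' deterministic set of starting points: one with all rate increases at 0
#' and one with all at `lam`. The baseline rate `lam`, division time `r`
#' and lower age bound `t_min` are fixed constants, not estimated.
#'
#' Samples whose age bound is infeasible (`S/r <= t_min`) are excluded with
#' a warning.
#'
#' @param cohort A `mutclock_cohort`.
#' @param lam Baseline alteration rate per division (from
#'   [compute_lambda()]).
#' @param r Cell division time, years per division.
#' @param t_min Lower bound on tumor age in divisions (default 50).
#' @param quad A [quad_spec()].
#' @param starts Optional list of starting parameter vectors in the
#'   internal transformed scale (advanced use; defaults to the
#'   deterministic two-start scheme).
#' @param fix_delta_zero If `TRUE`, all rate increases are pinned at 0
#'   (the "no mutators" model, used to demonstrate age overestimation).
#' @param weights Optional per-sample multiplicities (used by the
#'   bootstrap).
#' @param control List overriding `iter_max`, `eval_max`, `rel_tol`.
#' @return An object of class `mutclock_fit`: fitted [model_params()],
#'   log-likelihood, convergence diagnostics per start, and the data and
#'   quadrature used.
#' @export
fit_timing_model <- function(cohort, lam, r, t_min = 50,
                             quad = quad_spec(), starts = NULL,
                             fix_delta_zero = FALSE, weights = NULL,
                             control = list()) {
  ctrl <- modifyList(list(iter_max = 200, eval_max = 600, rel_tol = 1e-9),
                     control)
  young <- cohort$S / r <= t_min
  if (any(young)) {
    warning("excluding sample(s) with S/r <= t_min: ",
            paste(cohort$sample[young], collapse = ", "))
    cohort <- cohort_subset(cohort, !young)
    if (!is.null(weights)) weights <- weights[!young]
  }
  m <- cohort_matrices(cohort)
  J <- length(m$drivers)
  tmpl <- theta_template(J, fix_delta_zero)
  n_free <- length(tmpl$lower) - if (fix_delta_zero) J else 0
  if (nrow(cohort) < 2) {
    stop("cohort has fewer than 2 usable samples; the model is not identifiable")
  }
  if (nrow(cohort) < n_free) {
    warning("fewer samples (", nrow(cohort), ") than free parameters (",
            n_free, "); estimates will sit on boundaries or be unstable")
  }
  w <- if (is.null(weights)) rep(1, nrow(cohort)) else weights

  negll <- function(theta) {
    pv <- list(
      alpha = exp(theta[1]), beta = exp(theta[2]), rho = exp(theta[3]),
      lam = lam, r = r, t_min = t_min,
      alpha_j = exp(theta[3 + seq_len(J)]),
      beta_j = exp(theta[3 + J + seq_len(J)]),
      delta_j = lam * theta[3 + 2 * J + seq_len(J)],
      p_j = theta[3 + 3 * J + seq_len(J)]
    )
    res <- ll_eval_raw(m, pv, quad, weights = w)
    if (!is.finite(res$total)) return(1e10)
    -res$total
  }

  if (is.null(starts)) starts <- default_starts(m, lam, r, t_min, fix_delta_zero)
  runs <- lapply(starts, function(s0) {
    stopifnot(length(s0) == length(tmpl$lower))
    fit <- nlminb(s0, negll, lower = tmpl$lower, upper = tmpl$upper,
                  control = list(iter.max = ctrl$iter_max,
                                 eval.max = ctrl$eval_max,
                                 rel.tol = ctrl$rel_tol))
    fit$start_objective <- negll(s0)
    fit
  })
  ok <- vapply(runs, function(f) is.finite(f$objective) &&
                 f$objective < 1e10, logical(1))
  diag <- tibble::tibble(
    start = seq_along(runs),
    objective = vapply(runs, function(f) f$objective, numeric(1)),
    convergence = vapply(runs, function(f) f$convergence, numeric(1)),
    message = vapply(runs, function(f) f$message, character(1)),
    iterations = vapply(runs, function(f) f$iterations, numeric(1))
  )
  if (!any(ok)) {
    stop("no optimizer start converged to a finite objective:\n",
         paste(utils::capture.output(print(diag)), collapse = "\n"))
  }
  best_i <- which(ok)[which.min(diag$objective[ok])]
  best <- runs[[best_i]]
  params <- theta_to_params(best$par, J, lam, r, t_min, m$drivers)

  structure(
    list(params = params, logLik = -best$objective,
         convergence = best$convergence, message = best$message,
         iterations = best$iterations, start_used = best_i,
         starts_diagnostics = diag, theta = best$par,
         fix_delta_zero = fix_delta_zero,
         cohort = cohort, quad = quad,
         fixed = list(lam = lam, r = r, t_min = t_min),
         excluded = if (any(young)) cohort$sample[young] else character()),
    class = "mutclock_fit"
  )
}

#' @export
print.mutclock_fit <- function(x, ...) {
  cat("<mutclock_fit>\n")
  cat(sprintf("  samples: %d   drivers: %d   logLik: %.3f (start %d, %s)\n",
              nrow(x$cohort), nrow(x$params$drivers), x$logLik,
              x$start_used, x$message))
  print(x$params)
  invisible(x)
}

#' @describeIn fit_timing_model Fitted parameters as a tibble.
#' @param x A `mutclock_fit`.
#' @param ... Unused.
#' @method tidy mutclock_fit
#' @export
tidy.mutclock_fit <- function(x, ...) tidy(x$params)

#' @describeIn fit_timing_model One-row model summary.
#' @method glance mutclock_fit
#' @export
glance.mutclock_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$logLik, n_samples = nrow(x$cohort),
    n_drivers = nrow(x$params$drivers),
    convergence = x$convergence, iterations = x$iterations,
    fix_delta_zero = x$fix_delta_zero
  )
}

#' @export
logLik.mutclock_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$theta), class = "logLik")
}
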