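#' Bootstrap confidence intervals for parameters and posterior quantities
#'
#' Resamples whole samples with replacement, refits the model on each
#' replicate (warm-started from the point estimate), and recomputes the
#' posterior summaries of the original cohort under each replicate's
#' parameters. Percentile confidence intervals are formed at the given
#' level. The per-sample order confidence is the fraction of replicates
#' whose inferred driver order for that sample equals the point-estimate
#' order exactly.
#'
#' Replicates whose refit fails are logged and excluded; if more than 10%
#' fail the bootstrap aborts. A replicate in which a driver loses all of
#' its carriers contributes no rate-increase draw for that driver (`NA`).
#'
#' @param fit A `mutclock_fit`.
#' @param B Number of bootstrap replicates (default 400).
#' @param seed Integer seed; results are bit-reproducible given the seed.
#' @param level Confidence level (default 0.90).
#' @param control Optimizer control for the replicate refits (smaller
#'   budget than the point fit by default; replicates start at the point
#'   estimate, so few quasi-Newton iterations are needed).
#' @param quad Quadrature for the replicate refits and replicate
#'   posterior passes; defaults to the point fit's. A lighter rule here
#'   speeds large bootstraps considerably; the shared discretization
#'   error cancels to first order in percentile intervals.
#' @param keep_posteriors If `TRUE` (default), recompute the posterior
#'   summaries of the original cohort under every replicate's parameters
#'   (needed for posterior-quantity intervals, per-driver mean-time
#'   intervals and order confidence). Set to `FALSE` when only parameter
#'   intervals are required.
#' @return An object of class `mutclock_boot` with the replicate draws and
#'   percentile summaries.
#' @export
bootstrap_timing <- function(fit, B = 400, seed = 1, level = 0.90,
                             control = list(iter_max = 12, eval_max = 200,
                                            rel_tol = 1e-8),
                             quad = fit$quad,
                             keep_posteriors = TRUE) {
  stopifnot(inherits(fit, "mutclock_fit"), B >= 1, level > 0, level < 1)
  cohort <- fit$cohort
  m <- cohort_matrices(cohort)
  ns <- nrow(cohort)
  J <- length(m$drivers)

  set.seed(as.integer(seed))
  idx <- matrix(sample.int(ns, ns * B, replace = TRUE), nrow = B)

  npar <- length(fit$theta)
  theta_draws <- matrix(NA_real_, B, npar,
                        dimnames = list(NULL, theta_template(J)$names))
  delta_draws <- matrix(NA_real_, B, J, dimnames = list(NULL, m$drivers))
  postT_draws <- matrix(NA_real_, B, ns)
  postX_draws <- array(NA_real_, c(B, ns, J),
                       dimnames = list(NULL, m$sample, m$drivers))
  order_match <- matrix(NA, B, ns)

  point_post <- posterior_summaries(fit)
  point_orders <- point_post$order

  # Each replicate is refitted from two warm starts: the point estimate,
  # and the point estimate with the boundary-candidate rate increases
  # moved to zero. The second start lets replicates whose likelihood is
  # flat down to delta = 0 actually land on the boundary within the
  # capped iteration budget, which percentile intervals for a boundary
  # parameter require; replicates with genuine mutator signal reject it
  # on the objective. A driver is a boundary candidate when zeroing its
  # rate increase alone costs the point fit fewer than 3 log-likelihood
  # units (screened once, on the full cohort).
  fold_idx <- 3 + 2 * J + seq_len(J)
  theta0 <- fit$theta
  if (!fit$fix_delta_zero && any(fit$theta[fold_idx] > 0)) {
    for (j in seq_len(J)) {
      if (fit$theta[fold_idx[j]] == 0) next
      pinned <- fit$params
      pinned$drivers$delta_j[j] <- 0
      ll_pinned <- suppressWarnings(
        sum(likelihood_pass(m, pinned, fit$quad)$loglik))
      if (is.finite(ll_pinned) && fit$logLik - ll_pinned < 3) {
        theta0[fold_idx[j]] <- 0
      }
    }
  }
  rep_starts <- if (all(theta0 == fit$theta)) list(fit$theta) else
    list(fit$theta, theta0)

  failed <- integer()
  for (b in seq_len(B)) {
    tab <- tabulate(idx[b, ], nbins = ns)
    use <- which(tab > 0)
    sub <- cohort_subset(cohort, use)
    rep_fit <- try(suppressWarnings(fit_timing_model(
      sub, lam = fit$fixed$lam, r = fit$fixed$r, t_min = fit$fixed$t_min,
      quad = quad, starts = rep_starts,
      fix_delta_zero = fit$fix_delta_zero,
      weights = tab[use], control = control
    )), silent = TRUE)
    if (inherits(rep_fit, "try-error")) {
      failed <- c(failed, b)
      next
    }
    theta_draws[b, ] <- rep_fit$theta
    dj <- rep_fit$params$drivers$delta_j
    # a driver with no carriers in the replicate has an unidentified delta
    carriers <- colSums(m$A[idx[b, ], , drop = FALSE])
    dj[carriers == 0] <- NA_real_
    delta_draws[b, ] <- dj

    if (keep_posteriors) {
      pp <- likelihood_pass(m, rep_fit$params, quad, posteriors = TRUE)
      postT_draws[b, ] <- pp$postT
      postX_draws[b, , ] <- pp$postX
      for (i in seq_len(ns)) {
        alt <- m$drivers[m$A[i, ] == 1]
        ord <- if (length(alt)) alt[order(pp$postX[i, match(alt, m$drivers)],
                                          alt)] else character()
        order_match[b, i] <- identical(ord, point_orders[[i]])
      }
    }
  }
  if (length(failed) > 0.10 * B) {
    stop("bootstrap aborted: ", length(failed), " of ", B,
         " replicate fits failed")
  }
  if (length(failed)) {
    message(length(failed), " bootstrap replicate(s) failed and were excluded")
  }
  keep <- setdiff(seq_len(B), failed)

  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qlo <- function(v) if (all(is.na(v))) NA_real_ else
    quantile(v, probs[1], na.rm = TRUE, names = FALSE)
  qhi <- function(v) if (all(is.na(v))) NA_real_ else
    quantile(v, probs[2], na.rm = TRUE, names = FALSE)

  delta_ci <- tibble::tibble(
    driver = m$drivers,
    delta_hat = fit$params$drivers$delta_j,
    lower = apply(delta_draws[keep, , drop = FALSE], 2, qlo),
    upper = apply(delta_draws[keep, , drop = FALSE], 2, qhi),
    n_draws = apply(delta_draws[keep, , drop = FALSE], 2,
                    function(v) sum(!is.na(v)))
  )
  postT_ci <- NULL
  order_confidence <- NULL
  if (keep_posteriors) {
    # flag interval/point inversions for posterior quantities (allowed
    # under resampling, but worth a warning)
    postT_ci <- tibble::tibble(
      sample = m$sample,
      post_T = point_post$post_T,
      lower = apply(postT_draws[keep, , drop = FALSE], 2, qlo),
      upper = apply(postT_draws[keep, , drop = FALSE], 2, qhi)
    )
    inv <- postT_ci$post_T < postT_ci$lower | postT_ci$post_T > postT_ci$upper
    if (any(inv, na.rm = TRUE)) {
      warning(sum(inv, na.rm = TRUE),
              " sample(s) have point posterior age outside the bootstrap interval")
    }
    order_confidence <- tibble::tibble(
      sample = m$sample,
      order_str = point_post$order_str,
      order_confidence = colMeans(order_match[keep, , drop = FALSE])
    )
  }

  structure(
    list(B = B, B_used = length(keep), level = level, seed = seed,
         fit = fit, point_post = point_post,
         theta_draws = theta_draws[keep, , drop = FALSE],
         delta_draws = delta_draws[keep, , drop = FALSE],
         postT_draws = if (keep_posteriors)
           postT_draws[keep, , drop = FALSE] else NULL,
         postX_draws = if (keep_posteriors)
           postX_draws[keep, , , drop = FALSE] else NULL,
         delta_ci = delta_ci, postT_ci = postT_ci,
         order_confidence = order_confidence,
         failed = failed),
    class = "mutclock_boot"
  )
}

#' @export
print.mutclock_boot <- function(x, ...) {
  cat(sprintf("<mutclock_boot> %d/%d replicates, %g%% percentile intervals\n",
              x$B_used, x$B, 100 * x$level))
  print(x$delta_ci)
  invisible(x)
}

#' @describeIn bootstrap_timing Rate-increase estimates with percentile
#'   intervals, one row per driver.
#' @param x A `mutclock_boot`.
#' @param ... Unused.
#' @method tidy mutclock_boot
#' @export
tidy.mutclock_boot <- function(x, ...) x$delta_ci

#' Call mutator drivers from bootstrap intervals
#'
#' A driver is called a mutator when the lower bound of its percentile
#' confidence interval for the rate increase is strictly above zero.
#'
#' @param boot A `mutclock_boot`.
#' @return A tibble of the called mutators (`driver`, `delta_hat`, `lower`,
#'   `upper`, `pct_increase` = 100 * delta / lam), sorted by decreasing
#'   `delta_hat`. Zero rows when nothing is called.
#' @export
call_mutators <- function(boot) {
  stopifnot(inherits(boot, "mutclock_boot"))
  lam <- boot$fit$fixed$lam
  boot$delta_ci %>%
    dplyr::filter(!is.na(.data$lower), .data$lower > 0) %>%
    dplyr::mutate(pct_increase = 100 * .data$delta_hat / lam) %>%
    dplyr::arrange(dplyr::desc(.data$delta_hat))
}

#' Mean alteration time per driver
#'
#' The posterior mean alteration time of each driver averaged over the
#' samples in which it is altered, with a bootstrap percentile interval of
#' that mean when a `mutclock_boot` is supplied. Drivers altered in no
#' sample are omitted with a warning.
#'
#' @param posteriors A `mutclock_posterior` (see [posterior_summaries()]).
#' @param boot Optional `mutclock_boot` for confidence intervals.
#' @return A tibble: `driver`, `n_altered`, `mean_time`, and `lower`,
#'   `upper` when `boot` is given; drivers appear in catalog order.
#' @export
mean_alteration_times <- function(posteriors, boot = NULL) {
  drivers <- attr(posteriors, "drivers")
  out <- purrr::map_dfr(drivers, function(d) {
    x <- posteriors[[paste0("post_X_", d)]]
    carriers <- which(!is.na(x))
    if (!length(carriers)) {
      warning("driver ", d, " is altered in no sample; omitted")
      return(NULL)
    }
    row <- tibble::tibble(driver = d, n_altered = length(carriers),
                          mean_time = mean(x[carriers]))
    if (!is.null(boot) && is.null(boot$postX_draws)) {
      warning("bootstrap was run with keep_posteriors = FALSE; ",
              "no intervals for mean alteration times")
      boot <- NULL
    }
    if (!is.null(boot)) {
      j <- match(d, drivers)
      rep_means <- rowMeans(boot$postX_draws[, carriers, j, drop = FALSE])
      probs <- c((1 - boot$level) / 2, 1 - (1 - boot$level) / 2)
      row$lower <- quantile(rep_means, probs[1], na.rm = TRUE, names = FALSE)
      row$upper <- quantile(rep_means, probs[2], na.rm = TRUE, names = FALSE)
    }
    row
  })
  out
}
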