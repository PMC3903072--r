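#' Posterior summaries of tumor age and alteration times
#'
#' For each sample, the posterior mean of the tumor lineage age `T` and,
#' for each altered driver, the posterior mean alteration time `X` given
#' the observed data, computed with the same quadrature as the likelihood
#' (ratio of integrals). Germline drivers have `post_X = 0` exactly. The
#' per-sample driver order sorts the altered drivers by posterior mean
#' alteration time, ascending, with alphabetical tie-break.
#'
#' @param object A `mutclock_fit`, or a [model_params()] object (in which
#'   case `cohort` and `quad` must be given).
#' @param cohort,quad Override the fit's cohort / quadrature.
#' @param ... Unused.
#' @return A tibble of class `mutclock_posterior`: `sample`, `N`, `S`,
#'   `post_T`, one `post_X_<driver>` column per driver (`NA` where the
#'   driver is unaltered), `order` (list column of driver ids) and
#'   `order_str`.
#' @export
posterior_summaries <- function(object, cohort = NULL, quad = NULL, ...) {
  if (inherits(object, "mutclock_fit")) {
    params <- object$params
    if (is.null(cohort)) cohort <- object$cohort
    if (is.null(quad)) quad <- object$quad
  } else if (inherits(object, "mutclock_params")) {
    params <- object
    if (is.null(cohort)) stop("supply a cohort when passing raw parameters")
    if (is.null(quad)) quad <- quad_spec()
  } else {
    stop("`object` must be a mutclock_fit or mutclock_params")
  }
  m <- cohort_matrices(cohort)
  res <- likelihood_pass(m, params, quad, posteriors = TRUE)
  bad <- !is.finite(res$loglik)
  if (any(bad)) {
    stop("zero or undefined likelihood for sample(s): ",
         paste(m$sample[bad], collapse = ", "))
  }
  drivers <- m$drivers
  postX <- res$postX
  colnames(postX) <- drivers

  orders <- lapply(seq_len(nrow(cohort)), function(i) {
    alt <- drivers[m$A[i, ] == 1]
    if (!length(alt)) return(character())
    alt[order(postX[i, alt], alt)]
  })

  out <- tibble::tibble(
    sample = m$sample, N = m$N, S = m$S, post_T = res$postT
  )
  for (j in seq_along(drivers)) {
    out[[paste0("post_X_", drivers[j])]] <- postX[, j]
  }
  out$order <- orders
  out$order_str <- vapply(orders, paste, character(1), collapse = " -> ")
  structure(out, drivers = drivers, params = params,
            class = c("mutclock_posterior", class(out)))
}
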