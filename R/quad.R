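#' Quadrature specification for the marginal likelihood
#'
#' The per-sample marginal likelihood integrates the Poisson observation
#' density over the latent tumor age and, for each altered mutator driver,
#' its alteration time on `(0, t]`; the exposure term is integrated in
#' closed form. Both latent-variable integrals are carried out in the
#' probability space of the corresponding prior, which keeps them accurate
#' even when a fitted prior becomes sharply concentrated:
#'
#' * the tumor-age integral uses `n_t` Gauss-Legendre nodes placed at
#'   quantiles of the truncated tumor-age prior;
#' * each alteration-time integral uses `n_x` equal-mass quantile cells of
#'   the driver's Gamma prior (midpoint rule in prior mass, with the cell
#'   containing `t` contributing its partial mass).
#'
#' `quad_spec()` freezes these sizes so every likelihood value is
#' deterministic and reproducible.
#'
#' @param n_t Number of Gauss-Legendre nodes for the tumor-age integral.
#' @param n_x Number of prior-quantile cells for each alteration-time
#'   integral.
#' @return An object of class `mutclock_quad`.
#' @examples
#' quad_spec(16, 32)
#' @export
quad_spec <- function(n_t = 24, n_x = 64) {
  stopifnot(n_t >= 2, n_x >= 2)
  gt <- pracma::gaussLegendre(n_t, 0, 1)
  structure(
    list(n_t = as.integer(n_t), n_x = as.integer(n_x),
         t_nodes = gt$x, t_wts = gt$w),
    class = "mutclock_quad"
  )
}

#' @export
print.mutclock_quad <- function(x, ...) {
  cat(sprintf(
    "<mutclock_quad> %d Gauss-Legendre tumor-age nodes (prior-CDF space), %d alteration-time quantile cells\n",
    x$n_t, x$n_x))
  invisible(x)
}
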