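#' Model parameters for the passenger-count timing model
#'
#' Bundles the hyperparameters of the generative model together with its
#' fixed constants. The tumor lineage age \eqn{T} has a Gamma(`alpha`,
#' `beta`) prior truncated to `[t_min, S/r]` where `S` is the patient age in
#' years and `r` the cell division time in years per division. Each driver
#' `j` has an alteration-time prior that is a mixture of an atom `p_j` at
#' infinity (the driver never alters) and a Gamma(`alpha_j`, `beta_j`)
#' density on the positive axis, and a rate increase `delta_j >= 0` added to
#' the passenger alteration rate from its alteration time onwards. The
#' exposure term \eqn{E} is Exponential(`rho`). Passenger counts are Poisson
#' with per-lineage mean `lam * T + sum_j delta_j * (T - X_j) + E`.
#'
#' @param alpha,beta Shape and rate of the (truncated) Gamma prior on the
#'   tumor lineage age, in cell divisions.
#' @param rho Rate of the exponential prior on the exposure term; `1/rho` is
#'   the expected number of extra passenger alterations from unmodelled
#'   exposures (smoking, UV, ...).
#' @param lam Baseline passenger alteration rate per cell division (see
#'   [compute_lambda()]).
#' @param r Cell division time in years per division (e.g. `8/365` for an
#'   8-day division time).
#' @param t_min Lower bound on the tumor lineage age in cell divisions
#'   (default 50).
#' @param drivers A data frame with one row per driver and columns
#'   `driver`, `alpha_j`, `beta_j`, `delta_j`, `p_j`.
#'
#' @return An object of class `mutclock_params`.
#' @examples
#' model_params(
#'   alpha = 4, beta = 4 / 1100, rho = 1, lam = 0.01, r = 8 / 365,
#'   drivers = tibble::tibble(
#'     driver = c("D1", "D2"), alpha_j = 2, beta_j = 2 / 400,
#'     delta_j = c(0.02, 0), p_j = 0.4
#'   )
#' )
#' @export
model_params <- function(alpha, beta, rho, lam, r, t_min = 50,
                         drivers = NULL) {
  if (is.null(drivers)) {
    drivers <- tibble::tibble(
      driver = character(), alpha_j = numeric(), beta_j = numeric(),
      delta_j = numeric(), p_j = numeric()
    )
  }
  drivers <- tibble::as_tibble(drivers)
  need <- c("driver", "alpha_j", "beta_j", "delta_j", "p_j")
  if (!all(need %in% names(drivers))) {
    stop("`drivers` must have columns: ", paste(need, collapse = ", "))
  }
  stopifnot(
    alpha > 0, beta > 0, rho > 0, lam > 0, r > 0, t_min > 0,
    all(drivers$alpha_j > 0), all(drivers$beta_j > 0),
    all(drivers$delta_j >= 0),
    all(drivers$p_j >= 0), all(drivers$p_j <= 1),
    !anyDuplicated(drivers$driver)
  )
  structure(
    list(alpha = alpha, beta = beta, rho = rho, lam = lam, r = r,
         t_min = t_min, drivers = drivers[, need]),
    class = "mutclock_params"
  )
}

#' @export
print.mutclock_params <- function(x, ...) {
  cat("<mutclock_params>\n")
  cat(sprintf("  T prior: Gamma(shape=%.4g, rate=%.4g), truncated to [%g, S/r]\n",
              x$alpha, x$beta, x$t_min))
  cat(sprintf("  exposure: Exp(rho=%.4g); baseline rate lam=%.4g/division; r=%.4g yr/division\n",
              x$rho, x$lam, x$r))
  cat(sprintf("  %d driver(s):\n", nrow(x$drivers)))
  if (nrow(x$drivers)) print(x$drivers, n = Inf)
  invisible(x)
}

#' @describeIn model_params Flatten the parameter set to a two-column tibble
#'   (`parameter`, `value`) suitable for serialization.
#' @param x A `mutclock_params` object.
#' @param ... Unused.
#' @method tidy mutclock_params
#' @export
tidy.mutclock_params <- function(x, ...) {
  glob <- tibble::tibble(
    parameter = c("alpha", "beta", "rho", "lam", "r", "t_min"),
    driver = NA_character_,
    value = c(x$alpha, x$beta, x$rho, x$lam, x$r, x$t_min)
  )
  if (nrow(x$drivers)) {
    per <- tidyr::pivot_longer(x$drivers, -"driver",
                               names_to = "parameter", values_to = "value")
    glob <- dplyr::bind_rows(glob, per[, c("parameter", "driver", "value")])
  }
  glob
}

#' Serialize / restore model parameters
#'
#' Round-trips a `mutclock_params` object through a flat JSON file so a run
#' can be reproduced from its emitted configuration.
#'
#' @param params A `mutclock_params` object.
#' @param path File path.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   `mutclock_params` object.
#' @export
write_params <- function(params, path) {
  obj <- list(
    alpha = params$alpha, beta = params$beta, rho = params$rho,
    lam = params$lam, r = params$r, t_min = params$t_min,
    drivers = as.data.frame(params$drivers)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_params(
    alpha = obj$alpha, beta = obj$beta, rho = obj$rho, lam = obj$lam,
    r = obj$r, t_min = obj$t_min, drivers = tibble::as_tibble(obj$drivers)
  )
}
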