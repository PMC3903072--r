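#' Difference-in-means comparator for passenger counts
#'
#' For each driver, a Welch two-sample t-test of the passenger count `N`
#' between samples in which the driver is altered and the remaining
#' samples. This is the naive mutator screen: it cannot distinguish a
#' mutator from a driver that simply alters late (late drivers are also
#' enriched in high-count samples), so it is reported alongside the
#' model-based mutator calls to illustrate its false positives.
#'
#' @param cohort A `mutclock_cohort`.
#' @return A tibble: `driver`, `n_altered`, `n_other`, `mean_altered`,
#'   `mean_other`, `p_value` (`NA` when a group is empty or degenerate).
#' @export
comparator_test <- function(cohort) {
  m <- cohort_matrices(cohort)
  purrr::map_dfr(seq_along(m$drivers), function(j) {
    alt <- m$N[m$A[, j] == 1]
    oth <- m$N[m$A[, j] == 0]
    p <- if (length(alt) < 2 || length(oth) < 2) NA_real_ else
      tryCatch(t.test(alt, oth)$p.value, error = function(e) NA_real_)
    tibble::tibble(
      driver = m$drivers[j],
      n_altered = length(alt), n_other = length(oth),
      mean_altered = if (length(alt)) mean(alt) else NA_real_,
      mean_other = if (length(oth)) mean(oth) else NA_real_,
      p_value = p
    )
  })
}

#' Convert a tumor age in cell divisions to years
#'
#' @param mean_generations Tumor age in cell divisions.
#' @param division_time_days Cell division time in days.
#' @return Age in years (`generations * days / 365`).
#' @examples
#' age_in_years(749, 8) # 16.4 years
#' @export
age_in_years <- function(mean_generations, division_time_days) {
  stopifnot(mean_generations >= 0, division_time_days > 0)
  mean_generations * division_time_days / 365
}

#' Rate increase as a percentage of the baseline rate
#'
#' @param delta_j Estimated rate increase per division.
#' @param lam Baseline rate per division.
#' @param round_to Optional rounding unit in percent (e.g. 10 to round to
#'   the nearest 10%); `NULL` for no rounding.
#' @return `100 * delta_j / lam`, optionally rounded.
#' @examples
#' percent_increase(0.017, 0.01) # 170
#' @export
percent_increase <- function(delta_j, lam, round_to = NULL) {
  if (lam <= 0) stop("lam must be positive")
  out <- 100 * delta_j / lam
  if (!is.null(round_to)) out <- round(out / round_to) * round_to
  out
}

#' Cohort-level summary of posterior tumor ages
#'
#' Mean and 10th/90th percentiles (linear interpolation, `quantile`
#' type 7) of the per-sample posterior mean tumor age.
#'
#' @param posteriors A `mutclock_posterior`.
#' @return A list with `mean`, `p10`, `p90` (cell divisions) and `n`.
#' @export
cohort_age_summary <- function(posteriors) {
  stopifnot(nrow(posteriors) > 0)
  x <- posteriors$post_T
  list(mean = mean(x),
       p10 = quantile(x, 0.10, names = FALSE, type = 7),
       p90 = quantile(x, 0.90, names = FALSE, type = 7),
       n = length(x))
}

#' Write the analysis report files
#'
#' Writes the standard outputs of a run to a directory: the per-sample
#' posterior table (with intervals and order confidence when a bootstrap
#' is supplied), the per-driver mean alteration time table, the mutator
#' table, the order tree (indented text and Newick-like string), the
#' cohort age summary, and the resolved run configuration as JSON. Missing
#' components are skipped and flagged in the log.
#'
#' @param dir Output directory (created if needed).
#' @param fit A `mutclock_fit`.
#' @param posteriors A `mutclock_posterior` (computed from `fit` if
#'   `NULL`).
#' @param boot Optional `mutclock_boot`.
#' @param division_time_days Optional division time for the years
#'   conversion in the summary.
#' @return Invisibly, the vector of files written.
#' @export
render_report <- function(dir, fit, posteriors = NULL, boot = NULL,
                          division_time_days = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  log <- character()
  if (is.null(posteriors)) posteriors <- posterior_summaries(fit)

  # per-sample table
  per_sample <- posteriors
  per_sample$order <- NULL
  if (!is.null(boot) && !is.null(boot$postT_ci)) {
    per_sample <- dplyr::left_join(per_sample, boot$postT_ci[, -2],
                                   by = "sample") %>%
      dplyr::rename(post_T_lower = "lower", post_T_upper = "upper") %>%
      dplyr::left_join(boot$order_confidence[, c("sample", "order_confidence")],
                       by = "sample")
  } else {
    log <- c(log, "no bootstrap: per-sample intervals and order confidence omitted")
  }
  f <- file.path(dir, "per_sample_posteriors.tsv")
  readr::write_tsv(as.data.frame(per_sample), f)
  written <- c(written, f)

  # per-driver mean alteration times
  mt <- suppressWarnings(mean_alteration_times(posteriors, boot))
  f <- file.path(dir, "mean_alteration_times.tsv")
  readr::write_tsv(as.data.frame(mt), f)
  written <- c(written, f)

  # mutator table
  if (!is.null(boot)) {
    mut <- call_mutators(boot)
    f <- file.path(dir, "mutators.tsv")
    readr::write_tsv(as.data.frame(mut), f)
    written <- c(written, f)
  } else {
    log <- c(log, "no bootstrap: mutator calls omitted")
  }

  # order tree
  tree <- build_order_tree(posteriors)
  f <- file.path(dir, "order_tree.txt")
  writeLines(format(tree), f)
  written <- c(written, f)
  f <- file.path(dir, "order_tree.nwk")
  writeLines(tree_newick(tree), f)
  written <- c(written, f)

  # cohort summary
  cs <- cohort_age_summary(posteriors)
  lines <- c(
    sprintf("samples\t%d", cs$n),
    sprintf("mean_posterior_age_divisions\t%.6g", cs$mean),
    sprintf("p10_divisions\t%.6g", cs$p10),
    sprintf("p90_divisions\t%.6g", cs$p90),
    "percentile_method\tlinear interpolation (type 7)"
  )
  if (!is.null(division_time_days)) {
    lines <- c(lines, sprintf("mean_posterior_age_years\t%.6g",
                              age_in_years(cs$mean, division_time_days)))
  }
  f <- file.path(dir, "cohort_summary.tsv")
  writeLines(lines, f)
  written <- c(written, f)

  # resolved config
  cfg <- list(
    fixed = fit$fixed,
    quad = list(n_t = fit$quad$n_t, n_x = fit$quad$n_x),
    fix_delta_zero = fit$fix_delta_zero,
    bootstrap = if (!is.null(boot))
      list(B = boot$B, B_used = boot$B_used, level = boot$level,
           seed = boot$seed) else NULL,
    excluded_samples = fit$excluded,
    dropped_drivers = {
      dd <- attr(fit$cohort, "dropped_drivers")
      if (!is.null(dd)) as.data.frame(dd) else NULL
    },
    log = log
  )
  f <- file.path(dir, "run_config.json")
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA, null = "null")
  written <- c(written, f)
  f <- file.path(dir, "params.json")
  write_params(fit$params, f)
  written <- c(written, f)

  invisible(written)
}
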