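#' Construct a cohort table
#'
#' A cohort is the observed data of the timing model: one row per tumor
#' sample with the passenger alteration count `N`, the patient age `S` in
#' years, and per driver `j` an altered indicator column `A_<j>` and a
#' germline indicator column `G_<j>` (`G = 1` implies `A = 1`). Usually
#' built by [build_cohort()] or [simulate_cohort()]; `as_cohort()` validates
#' and tags a hand-made data frame.
#'
#' @param data A data frame with columns `sample`, `N`, `S` and `A_*`/`G_*`
#'   indicator columns for each driver.
#' @param drivers Character vector of driver identifiers; defaults to the
#'   drivers implied by the `A_*` columns.
#' @param data_kind `"mutation"` or `"cna"`.
#' @return A tibble of class `mutclock_cohort` with attributes `drivers`
#'   and `data_kind`.
#' @export
as_cohort <- function(data, drivers = NULL, data_kind = c("mutation", "cna")) {
  data_kind <- match.arg(data_kind)
  data <- tibble::as_tibble(data)
  if (is.null(drivers)) {
    drivers <- sub("^A_", "", grep("^A_", names(data), value = TRUE))
  }
  need <- c("sample", "N", "S", paste0("A_", drivers), paste0("G_", drivers))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(is.na(data$S))) {
    stop("sample(s) with missing age: ",
         paste(data$sample[is.na(data$S)], collapse = ", "))
  }
  stopifnot(all(data$N >= 0), all(data$S > 0))
  A <- as.matrix(data[paste0("A_", drivers)])
  G <- as.matrix(data[paste0("G_", drivers)])
  if (any(G == 1 & A == 0)) {
    stop("germline indicator set without altered indicator (G=1 requires A=1)")
  }
  out <- data[c("sample", "N", "S", paste0("A_", drivers), paste0("G_", drivers))]
  structure(out,
            drivers = drivers, data_kind = data_kind,
            class = c("mutclock_cohort", class(out)))
}

#' Drivers recorded in a cohort
#' @param cohort A `mutclock_cohort`.
#' @return Character vector of driver identifiers.
#' @export
cohort_drivers <- function(cohort) attr(cohort, "drivers")

# Internal: pull the model's matrix view out of a cohort tibble.
cohort_matrices <- function(cohort) {
  drivers <- cohort_drivers(cohort)
  list(
    sample = cohort$sample,
    N = as.integer(cohort$N),
    S = as.numeric(cohort$S),
    A = matrix(as.integer(as.matrix(cohort[paste0("A_", drivers)])),
               nrow = nrow(cohort),
               dimnames = list(NULL, drivers)),
    G = matrix(as.integer(as.matrix(cohort[paste0("G_", drivers)])),
               nrow = nrow(cohort),
               dimnames = list(NULL, drivers)),
    drivers = drivers
  )
}

# Keep cohort attributes through dplyr row subsetting used internally.
cohort_subset <- function(cohort, idx) {
  out <- cohort[idx, , drop = FALSE]
  attr(out, "drivers") <- attr(cohort, "drivers")
  attr(out, "data_kind") <- attr(cohort, "data_kind")
  class(out) <- class(cohort)
  out
}
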