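#' Default parameter set for simulation studies
#'
#' Study conditions for the forward simulator, chosen to match the scale of
#' copy-number cohorts: baseline rate `lam = 0.01` alterations per division
#' (about ten passenger events over a thousand-division lineage), a
#' truncated-Gamma tumor-age prior with untruncated mean 1100 divisions,
#' an 8-day cell division time, exposure mean 1 event, and two drivers —
#' `M1`, a mutator tripling the passenger rate (`delta = 2 * lam`), and
#' `P1`, a non-mutator — with alteration-time priors of mean 400 divisions
#' and never-alters probability 0.4.
#'
#' @param delta_mutator Rate increase of the mutator driver `M1`
#'   (default `2 * lam`).
#' @param lam Baseline rate per division.
#' @return A [model_params()] object.
#' @export
sim_params <- function(delta_mutator = 2 * lam, lam = 0.01) {
  model_params(
    alpha = 4, beta = 4 / 1100, rho = 1, lam = lam, r = 8 / 365,
    t_min = 50,
    drivers = tibble::tibble(
      driver = c("M1", "P1"),
      alpha_j = 2, beta_j = 2 / 400,
      delta_j = c(delta_mutator, 0),
      p_j = 0.4
    )
  )
}

# Inverse-CDF draw from Gamma(alpha, beta) truncated to [lo, hi]
rtrunc_gamma <- function(n, alpha, beta, lo, hi) {
  plo <- pgamma(lo, alpha, rate = beta)
  phi <- pgamma(hi, alpha, rate = beta)
  qgamma(plo + runif(n) * (phi - plo), alpha, rate = beta)
}

#' Simulate a cohort from the generative model
#'
#' Runs the model forward: per sample, a patient age `S` is drawn uniformly
#' over `age_range` (integer years), the tumor age `T` from the truncated
#' Gamma prior on `[t_min, S/r]`, each driver's alteration time `X` from
#' its atom-plus-Gamma prior (germline drivers are forced to `X = 0` with
#' the given probability), the exposure `E` from its exponential prior,
#' and the passenger count `N` from a Poisson with the model rate. Each
#' sample uses its own seeded random substream, so enlarging the cohort
#' does not reshuffle earlier samples.
#'
#' @param n_samples Number of samples.
#' @param params True [model_params()].
#' @param age_range Patient age range in years (inclusive, integer ages).
#' @param germline_prob Named numeric vector of per-driver germline
#'   probabilities (missing drivers default to 0).
#' @param seed Integer seed; the cohort is bit-reproducible given the seed.
#' @return A list with `cohort` (a `mutclock_cohort`) and `truth` (tibble
#'   of the latent `T`, per-driver `X` — `Inf` when the driver never
#'   alters —, `E` and the realized Poisson mean `mu`).
#' @examples
#' sim <- simulate_cohort(20, sim_params(), seed = 1)
#' sim$cohort
#' @export
simulate_cohort <- function(n_samples, params = sim_params(),
                            age_range = c(40, 80), germline_prob = NULL,
                            seed = 1) {
  stopifnot(n_samples >= 1)
  d <- params$drivers
  J <- nrow(d)
  gp <- setNames(rep(0, J), d$driver)
  if (!is.null(germline_prob)) {
    stopifnot(!is.null(names(germline_prob)),
              all(names(germline_prob) %in% d$driver))
    gp[names(germline_prob)] <- germline_prob
  }

  # per-sample substreams: a prefix-stable seed sequence drawn once
  set.seed(as.integer(seed))
  sample_seeds <- sample.int(.Machine$integer.max - 1L, n_samples,
                             replace = TRUE)

  S <- integer(n_samples)
  Tt <- numeric(n_samples)
  X <- matrix(NA_real_, n_samples, J, dimnames = list(NULL, d$driver))
  A <- matrix(0L, n_samples, J)
  G <- matrix(0L, n_samples, J)
  E <- numeric(n_samples)
  mu <- numeric(n_samples)
  N <- integer(n_samples)

  for (i in seq_len(n_samples)) {
    set.seed(sample_seeds[i])
    repeat {
      s <- floor(runif(1, age_range[1], age_range[2] + 1))
      if (s / params$r > params$t_min) break
      warning("patient age incompatible with t_min; resampling")
    }
    S[i] <- s
    Tt[i] <- rtrunc_gamma(1, params$alpha, params$beta,
                          params$t_min, s / params$r)
    for (j in seq_len(J)) {
      if (runif(1) < gp[j]) {
        X[i, j] <- 0; A[i, j] <- 1L; G[i, j] <- 1L
      } else if (runif(1) < d$p_j[j]) {
        X[i, j] <- Inf
      } else {
        X[i, j] <- rgamma(1, d$alpha_j[j], rate = d$beta_j[j])
        if (X[i, j] <= Tt[i]) A[i, j] <- 1L
      }
    }
    E[i] <- rexp(1, rate = params$rho)
    altered <- which(A[i, ] == 1L)
    mu[i] <- params$lam * Tt[i] +
      sum(d$delta_j[altered] * (Tt[i] - X[i, altered])) + E[i]
    N[i] <- rpois(1, mu[i])
  }

  ids <- sprintf("S%04d", seq_len(n_samples))
  cohort <- tibble::tibble(sample = ids, N = N, S = as.numeric(S))
  for (j in seq_len(J)) cohort[[paste0("A_", d$driver[j])]] <- A[, j]
  for (j in seq_len(J)) cohort[[paste0("G_", d$driver[j])]] <- G[, j]
  cohort <- as_cohort(cohort, drivers = d$driver, data_kind = "cna")

  truth <- tibble::tibble(sample = ids, T = Tt, E = E, mu = mu)
  for (j in seq_len(J)) truth[[paste0("X_", d$driver[j])]] <- X[, j]

  list(cohort = cohort, truth = truth)
}

#' Toy raw files with planted preprocessing outcomes
#'
#' Emits small segment / region / mutation / age tables whose
#' classification by the preprocessing rules is known by construction:
#' segments exactly at the log2 thresholds (dropped, strict inequality), a
#' driver segment at exactly two-thirds overlap (discarded, strict rule),
#' a clearly qualifying driver segment, passenger segments placed beyond
#' the distance rule with a pair close enough to merge, and a satellite
#' region duplicating a main region's alteration pattern.
#'
#' @param dir Optional directory; when given, the four tables are written
#'   as TSV files (`segments.tsv`, `regions.tsv`, `mutations.tsv`,
#'   `ages.tsv`).
#' @return A list of tibbles `segments`, `regions`, `mutations`, `ages`,
#'   plus `expected`, a list describing the planted outcomes.
#' @export
simulate_raw_files <- function(dir = NULL) {
  regions <- tibble::tibble(
    region_id = c("amp_1", "del_1", "amp_sat"),
    chrom = c("1", "2", "1"),
    start = c(10e6, 30e6, 13e6),
    end = c(11e6 - 1, 31e6 - 1, 14e6 - 1),
    alt_type = c("amplification", "deletion", "amplification")
  )
  segments <- tibble::tibble(
    sample = c("s1", "s1", "s1", "s2", "s2", "s2", "s2", "s3"),
    chrom = c("1", "1", "2", "1", "2", "2", "2", "1"),
    start = c(
      10e6,            # s1: covers amp_1 fully -> driver
      20e6,            # s1: >= 1e6 from every region end -> passenger
      30e6,            # s1: log2 exactly at threshold -> dropped
      10e6,            # s2: exactly 2/3 of amp_1 -> discarded (strict >)
      35e6,            # s2: far deletion -> passenger
      35.2e6,          # s2: 149999 bp gap from previous -> not merged
      35.35e6 + 50000, # s2: 49999 bp gap from previous -> merged
      13e6             # s3: covers amp_sat -> driver of the satellite
    ),
    end = c(
      11e6 - 1, 20.5e6, 30.5e6,
      10e6 + (2 / 3) * 1e6 - 1, # overlap exactly (2/3) * region length
      35.05e6, 35.3e6, 35.45e6,
      14e6 - 1
    ),
    log2_ratio = c(1.6, 1.4, 1.0, 1.8, -1.5, -1.3, -2.0, 1.2)
  )
  mutations <- tibble::tibble(
    sample = c("s1", "s1", "s2", "s3", "s3"),
    gene = c("DRV1", "PSG1", "DRV1", "DRV2", "PSG2"),
    is_germline = c(FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  ages <- tibble::tibble(sample = c("s1", "s2", "s3"),
                         age_years = c(61, 55, 70))
  expected <- list(
    dropped_segments = 1L,          # the log2 == 1.0 row
    s1_driver_region = "amp_1",
    s2_discarded = TRUE,            # exact 2/3 overlap fails the strict rule
    s2_merged_passengers = 2L,      # 3 deletion calls -> 2 after merging
    germline_driver = c(sample = "s2", gene = "DRV1")
  )
  out <- list(segments = segments, regions = regions,
              mutations = mutations, ages = ages, expected = expected)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(segments, file.path(dir, "segments.tsv"))
    readr::write_tsv(regions, file.path(dir, "regions.tsv"))
    m <- mutations
    m$status <- ifelse(m$is_germline, "germline", "somatic")
    readr::write_tsv(m[, c("sample", "gene", "status")],
                     file.path(dir, "mutations.tsv"))
    readr::write_tsv(ages, file.path(dir, "ages.tsv"))
  }
  out
}
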