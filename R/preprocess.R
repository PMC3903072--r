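#' Call copy-number alterations from segmented data
#'
#' Keeps the segments whose log2 copy-number change exceeds the
#' amplification threshold (strictly `> amp_threshold`) or falls below the
#' deletion threshold (strictly `< del_threshold`); everything in between
#' is not a CNA and is dropped. Coordinates are 1-based inclusive (SEG
#' convention).
#'
#' @param segments Data frame with columns `sample`, `chrom`, `start`,
#'   `end`, `log2_ratio`.
#' @param amp_threshold,del_threshold log2-ratio thresholds (defaults +1 /
#'   -1).
#' @return A tibble of CNA calls: `sample`, `chrom`, `start`, `end`,
#'   `alt_type` (`"amplification"` or `"deletion"`), `role` (`NA`, set by
#'   [classify_cnas()]), `region_id` (`NA`).
#' @examples
#' segs <- tibble::tibble(
#'   sample = "s1", chrom = "1", start = c(1, 100, 200),
#'   end = c(50, 150, 250), log2_ratio = c(1.5, -1.2, 0.5)
#' )
#' call_cnas(segs) # two calls; the 0.5 segment is dropped
#' @export
call_cnas <- function(segments, amp_threshold = 1, del_threshold = -1) {
  segments <- tibble::as_tibble(segments)
  need <- c("sample", "chrom", "start", "end", "log2_ratio")
  missing_cols <- setdiff(need, names(segments))
  if (length(missing_cols)) {
    stop("segments are missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(
    is.na(segments$start) | is.na(segments$end) | is.na(segments$log2_ratio) |
      segments$start > segments$end |
      is.na(segments$chrom) | segments$chrom == ""
  )
  if (length(bad)) {
    stop("malformed segment row(s) at line(s): ",
         paste(head(bad, 10), collapse = ", "))
  }
  segments %>%
    dplyr::filter(.data$log2_ratio > amp_threshold |
                    .data$log2_ratio < del_threshold) %>%
    dplyr::mutate(
      alt_type = dplyr::if_else(.data$log2_ratio > amp_threshold,
                                "amplification", "deletion"),
      role = NA_character_,
      region_id = NA_character_
    ) %>%
    dplyr::select("sample", "chrom", "start", "end", "alt_type",
                  "role", "region_id")
}

# distance between the nearest point of [s, e] and a single coordinate
.pt_dist <- function(s, e, p) {
  ifelse(p < s, s - p, ifelse(p > e, p - e, 0))
}

#' Classify CNA calls as driver, passenger or discarded
#'
#' A call is a **passenger** if it lies at least `far_dist` base pairs from
#' both ends of every recurrent region on the same chromosome (regions of
#' either type count). It is a **driver** associated with a region if it
#' overlaps a region of the same type for strictly more than
#' `overlap_frac` of the region's length (overlap length computed on
#' 1-based inclusive intervals). Calls satisfying neither rule are
#' **discarded**. The three outcomes partition the calls. If several
#' regions qualify, the one with the largest overlap fraction (ties: the
#' smaller start) is recorded.
#'
#' @param calls Output of [call_cnas()].
#' @param regions Data frame of recurrently altered regions with columns
#'   `region_id`, `chrom`, `start`, `end`, `alt_type`.
#' @param far_dist Passenger distance rule in bp (default `1e6`).
#' @param overlap_frac Driver overlap rule as a fraction of region length
#'   (default `2/3`, strict).
#' @return `calls` with `role` and `region_id` filled in.
#' @export
classify_cnas <- function(calls, regions, far_dist = 1e6,
                          overlap_frac = 2 / 3) {
  calls <- tibble::as_tibble(calls)
  regions <- tibble::as_tibble(regions)
  stopifnot(all(regions$start <= regions$end))
  n <- nrow(calls)
  role <- character(n)
  region_id <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cc <- calls[i, ]
    same_chr <- regions[regions$chrom == cc$chrom, , drop = FALSE]
    if (nrow(same_chr) == 0) {
      role[i] <- "passenger"
      next
    }
    d_ends <- pmin(.pt_dist(cc$start, cc$end, same_chr$start),
                   .pt_dist(cc$start, cc$end, same_chr$end))
    if (all(d_ends >= far_dist)) {
      role[i] <- "passenger"
      next
    }
    same_type <- same_chr[same_chr$alt_type == cc$alt_type, , drop = FALSE]
    if (nrow(same_type)) {
      ov <- pmax(0, pmin(cc$end, same_type$end) -
                   pmax(cc$start, same_type$start) + 1)
      frac <- ov / (same_type$end - same_type$start + 1)
      hit <- which(frac > overlap_frac)
      if (length(hit)) {
        best <- hit[order(-frac[hit], same_type$start[hit])][1]
        role[i] <- "driver"
        region_id[i] <- same_type$region_id[best]
        next
      }
    }
    role[i] <- "discarded"
  }
  calls$role <- role
  calls$region_id <- region_id
  calls
}

#' Merge nearby passenger CNAs of the same type
#'
#' Within each (sample, chromosome, alteration type), passenger calls
#' separated by strictly fewer than `gap` intervening base pairs are
#' replaced by a single call spanning their union. Merging is transitive
#' and idempotent. The inter-call gap is the number of bases strictly
#' between two calls (`start2 - end1 - 1` on 1-based inclusive intervals).
#'
#' @param calls Passenger CNA calls (all rows must have
#'   `role == "passenger"`).
#' @param gap Merge distance in bp (default `1e5`).
#' @return A tibble of merged passenger calls.
#' @export
merge_passenger_cnas <- function(calls, gap = 1e5) {
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0) return(calls)
  if (!all(calls$role == "passenger")) {
    stop("merge_passenger_cnas() expects only passenger calls")
  }
  calls %>%
    dplyr::group_by(.data$sample, .data$chrom, .data$alt_type) %>%
    dplyr::arrange(.data$start, .data$end, .by_group = TRUE) %>%
    dplyr::mutate(
      new_block = .data$start - dplyr::lag(cummax(.data$end),
                                           default = -Inf) - 1 >= gap,
      block = cumsum(.data$new_block)
    ) %>%
    dplyr::group_by(.data$block, .add = TRUE) %>%
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      role = "passenger", region_id = NA_character_,
      .groups = "drop"
    ) %>%
    dplyr::select("sample", "chrom", "start", "end", "alt_type",
                  "role", "region_id") %>%
    dplyr::arrange(.data$sample, .data$chrom, .data$start)
}

#' Remove satellite regions with duplicated alteration patterns
#'
#' Recurrent-region finders can report several neighbouring regions for
#' what is a single underlying event: the satellite regions are altered in
#' (almost) the same set of samples as a main region. Among
#' same-chromosome, same-type region pairs whose sample-set Jaccard
#' similarity is at least `similarity_threshold`, only the region altered
#' in the most samples is retained (ties broken by smaller start
#' coordinate); similarity groups are closed transitively.
#'
#' @param regions Data frame of regions (`region_id`, `chrom`, `start`,
#'   `end`, `alt_type`).
#' @param alteration_matrix Logical/0-1 matrix, regions in rows (rownames
#'   must be `region_id`), samples in columns.
#' @param similarity_threshold Jaccard similarity at or above which two
#'   regions are considered the same event (default 0.6).
#' @return The retained regions; the removals are attached as attribute
#'   `"removed"` (a tibble with `region_id` and `kept_region`) and reported
#'   via `message()`.
#' @export
dedupe_satellite_regions <- function(regions, alteration_matrix,
                                     similarity_threshold = 0.6) {
  regions <- tibble::as_tibble(regions)
  M <- alteration_matrix[regions$region_id, , drop = FALSE] > 0
  counts <- rowSums(M)
  n <- nrow(regions)
  # union-find over similar same-chromosome same-type pairs
  parent <- seq_len(n)
  find2 <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (k in seq(i + 1, n)) {
        if (regions$chrom[i] != regions$chrom[k] ||
            regions$alt_type[i] != regions$alt_type[k]) next
        inter <- sum(M[i, ] & M[k, ])
        uni <- sum(M[i, ] | M[k, ])
        jac <- if (uni == 0) 0 else inter / uni
        if (jac >= similarity_threshold) {
          ri <- find2(i); rk <- find2(k)
          if (ri != rk) parent[rk] <- ri
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find2, integer(1))
  keep <- logical(n)
  kept_of_comp <- character(n)
  for (cpt in unique(comp)) {
    idx <- which(comp == cpt)
    best <- idx[order(-counts[idx], regions$start[idx])][1]
    keep[best] <- TRUE
    kept_of_comp[idx] <- regions$region_id[best]
  }
  removed <- tibble::tibble(
    region_id = regions$region_id[!keep],
    kept_region = kept_of_comp[!keep]
  )
  if (nrow(removed)) {
    message("removed ", nrow(removed), " satellite region(s): ",
            paste(removed$region_id, collapse = ", "))
  }
  out <- regions[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Assemble the model's observed data from preprocessed alterations
#'
#' Builds the per-sample cohort table (passenger count `N`, patient age
#' `S`, driver indicators `A`/`G`) from either a mutation table or
#' classified CNA calls. Drivers altered in at most `min_recurrence`
#' samples are dropped (unless force-kept), and drivers altered in more
#' than `max_frequency` of samples are dropped with a warning, since their
#' parameters cannot be estimated from the few unaltered samples.
#'
#' For mutation data, `N` counts somatic mutations in genes outside the
#' driver catalog; a driver gene's `A` is set by any mutation and `G` by a
#' germline mutation (a germline record sets both). For CNA data, `N`
#' counts merged passenger calls and `A` is set by driver calls (`G` is
#' always 0: there are no germline focal CNAs in these data).
#'
#' @param data For `data_kind = "mutation"`, a tibble with `sample`,
#'   `gene`, `is_germline`. For `"cna"`, classified calls from
#'   [classify_cnas()] with passengers already merged by
#'   [merge_passenger_cnas()] (pass the combined driver + merged-passenger
#'   rows).
#' @param drivers For mutation data, a character vector of driver gene
#'   symbols; for CNA data, the regions table (after any
#'   [dedupe_satellite_regions()]).
#' @param ages Tibble with `sample` and `age_years` for every sample.
#' @param data_kind `"mutation"` or `"cna"`.
#' @param min_recurrence Drop drivers altered in `<= min_recurrence`
#'   samples (default 10).
#' @param max_frequency Drop drivers altered in more than this fraction of
#'   samples, with a warning (default 0.9).
#' @param keep Driver identifiers exempt from the recurrence filter.
#' @return A `mutclock_cohort` tibble; dropped drivers are recorded in the
#'   `"dropped_drivers"` attribute.
#' @export
build_cohort <- function(data, drivers, ages,
                         data_kind = c("mutation", "cna"),
                         min_recurrence = 10, max_frequency = 0.9,
                         keep = character()) {
  data_kind <- match.arg(data_kind)
  data <- tibble::as_tibble(data)
  ages <- tibble::as_tibble(ages)
  stopifnot(all(c("sample", "age_years") %in% names(ages)))

  if (data_kind == "mutation") {
    driver_ids <- as.character(drivers)
    missing_age <- setdiff(unique(data$sample), ages$sample)
    if (length(missing_age)) {
      stop("sample(s) with missing age: ", paste(missing_age, collapse = ", "))
    }
    samples <- ages$sample
    passengers <- data %>%
      dplyr::filter(!.data$is_germline, !(.data$gene %in% driver_ids)) %>%
      dplyr::count(.data$sample, name = "N")
    altered <- data %>% dplyr::filter(.data$gene %in% driver_ids)
    A <- matrix(0L, length(samples), length(driver_ids),
                dimnames = list(samples, driver_ids))
    G <- A
    if (nrow(altered)) {
      A[cbind(match(altered$sample, samples),
              match(altered$gene, driver_ids))] <- 1L
      germ <- altered[altered$is_germline, , drop = FALSE]
      if (nrow(germ)) {
        G[cbind(match(germ$sample, samples),
                match(germ$gene, driver_ids))] <- 1L
      }
    }
    N <- passengers$N[match(samples, passengers$sample)]
    N[is.na(N)] <- 0L
  } else {
    stopifnot(all(c("role", "region_id") %in% names(data)))
    driver_ids <- as.character(drivers$region_id)
    missing_age <- setdiff(unique(data$sample), ages$sample)
    if (length(missing_age)) {
      stop("sample(s) with missing age: ", paste(missing_age, collapse = ", "))
    }
    samples <- ages$sample
    passengers <- data %>%
      dplyr::filter(.data$role == "passenger") %>%
      dplyr::count(.data$sample, name = "N")
    drv <- data %>%
      dplyr::filter(.data$role == "driver",
                    .data$region_id %in% driver_ids) %>%
      dplyr::distinct(.data$sample, .data$region_id)
    A <- matrix(0L, length(samples), length(driver_ids),
                dimnames = list(samples, driver_ids))
    G <- A
    if (nrow(drv)) {
      A[cbind(match(drv$sample, samples),
              match(drv$region_id, driver_ids))] <- 1L
    }
    N <- passengers$N[match(samples, passengers$sample)]
    N[is.na(N)] <- 0L
  }

  counts <- colSums(A)
  too_rare <- counts <= min_recurrence & !(driver_ids %in% keep)
  too_common <- counts > max_frequency * length(samples)
  if (any(too_common)) {
    warning("dropping near-ubiquitous driver(s) altered in > ",
            round(100 * max_frequency), "% of samples: ",
            paste(driver_ids[too_common], collapse = ", "))
  }
  retained <- driver_ids[!too_rare & !too_common]
  dropped <- tibble::tibble(
    driver = driver_ids[too_rare | too_common],
    n_altered = counts[too_rare | too_common],
    reason = ifelse(too_common[too_rare | too_common],
                    "near_ubiquitous", "low_recurrence")
  )

  if (!length(retained)) {
    stop("no drivers retained after the recurrence/frequency filters")
  }
  out <- tibble::tibble(sample = samples, N = as.integer(N),
                        S = ages$age_years)
  for (dd in retained) out[[paste0("A_", dd)]] <- unname(A[, dd])
  for (dd in retained) out[[paste0("G_", dd)]] <- unname(G[, dd])
  out <- as_cohort(out, drivers = retained, data_kind = data_kind)
  attr(out, "dropped_drivers") <- dropped
  out
}

#' Baseline alteration rates per cell division
#'
#' The nucleotide mutation rate per cell division is the experimentally
#' determined per-base-pair rate (default `1e-9`) times the number of base
#' pairs sequenced in non-driver genes. The CNA rate is not directly
#' measurable; it is calibrated through the ratio `R` of the average number
#' of passenger CNAs to the average number of passenger mutations per
#' sample: `lambda_cna = R * lambda_mut`.
#'
#' @param bp_sequenced Base pairs sequenced in non-driver genes.
#' @param per_bp_rate Mutation rate per base pair per cell division.
#' @param passenger_mut_mean,passenger_cna_mean Average passenger mutation
#'   and CNA counts per sample (both optional; needed for `lambda_cna`).
#' @return A list with `lambda_mut`, `lambda_cna` and `R` (the latter two
#'   `NA` when CNA means are not supplied).
#' @examples
#' compute_lambda(3e7) # lambda_mut = 0.03
#' compute_lambda(3e7, passenger_mut_mean = 8, passenger_cna_mean = 4)
#' @export
compute_lambda <- function(bp_sequenced, per_bp_rate = 1e-9,
                           passenger_mut_mean = NULL,
                           passenger_cna_mean = NULL) {
  stopifnot(bp_sequenced >= 0, per_bp_rate > 0)
  if (bp_sequenced == 0) {
    warning("bp_sequenced = 0: baseline mutation rate is degenerate (0)")
  }
  lambda_mut <- per_bp_rate * bp_sequenced
  lambda_cna <- NA_real_
  R <- NA_real_
  if (!is.null(passenger_cna_mean)) {
    if (is.null(passenger_mut_mean) || passenger_mut_mean == 0) {
      stop("passenger_mut_mean must be positive to calibrate lambda_cna")
    }
    R <- passenger_cna_mean / passenger_mut_mean
    lambda_cna <- R * lambda_mut
  }
  list(lambda_mut = lambda_mut, lambda_cna = lambda_cna, R = R)
}
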