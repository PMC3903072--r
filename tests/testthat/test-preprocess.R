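test_that("CNA calling applies strict log2 thresholds", {
  segs <- tibble::tibble(
    sample = "s1", chrom = "1",
    start = c(1, 101, 201, 301, 401),
    end = c(100, 200, 300, 400, 500),
    log2_ratio = c(1.5, -1.2, 0.5, 1.0, -1.0)
  )
  calls <- call_cnas(segs)
  expect_equal(nrow(calls), 2)  # the 0.5, 1.0 and -1.0 rows are dropped
  expect_equal(calls$alt_type, c("amplification", "deletion"))
  expect_true(all(is.na(calls$role)))
})

test_that("malformed segment rows are reported with their line number", {
  segs <- tibble::tibble(
    sample = "s1", chrom = c("1", "1", ""),
    start = c(1, 500, 10), end = c(100, 400, 20),
    log2_ratio = c(1.5, 2, 2)
  )
  expect_error(call_cnas(segs), "line")
  expect_error(call_cnas(segs), "2")
})

test_that("classification partitions calls into driver/passenger/discarded", {
  regions <- tibble::tibble(
    region_id = "amp_1", chrom = "1", start = 10e6, end = 11e6 - 1,
    alt_type = "amplification"
  )
  calls <- tibble::tibble(
    sample = "s",
    chrom = "1",
    start = c(10e6,                        # 100% overlap -> driver
              10e6,                        # exactly 2/3 overlap -> discarded
              10e6,                        # 50% overlap, touching -> discarded
              12.1e6,                      # >= 1e6 from both ends -> passenger
              11.5e6),                     # 0.5e6 from the end -> discarded
    end = c(11e6 - 1,
            10e6 + (2 / 3) * 1e6 - 1,
            10.5e6 - 1,
            12.5e6,
            11.6e6),
    alt_type = "amplification", role = NA_character_,
    region_id = NA_character_
  )
  out <- classify_cnas(calls, regions)
  expect_equal(out$role,
               c("driver", "discarded", "discarded", "passenger", "discarded"))
  expect_equal(out$region_id[1], "amp_1")
  expect_true(all(out$role %in% c("driver", "passenger", "discarded")))
})

test_that("the passenger distance rule counts regions of either type", {
  regions <- tibble::tibble(
    region_id = "del_1", chrom = "2", start = 30e6, end = 31e6 - 1,
    alt_type = "deletion"
  )
  amp_near_del_region <- tibble::tibble(
    sample = "s", chrom = "2", start = 31.5e6, end = 31.6e6,
    alt_type = "amplification", role = NA_character_, region_id = NA_character_
  )
  out <- classify_cnas(amp_near_del_region, regions)
  expect_equal(out$role, "discarded")  # close to a region, wrong type
  # a call on a chromosome with no regions is a passenger
  other_chrom <- amp_near_del_region
  other_chrom$chrom <- "7"
  expect_equal(classify_cnas(other_chrom, regions)$role, "passenger")
})

test_that("nearby same-type passenger calls merge transitively", {
  base <- tibble::tibble(
    sample = "s", chrom = "3", alt_type = "deletion",
    role = "passenger", region_id = NA_character_
  )
  calls <- dplyr::bind_rows(
    dplyr::mutate(base, start = 1e6, end = 1.1e6),
    dplyr::mutate(base, start = 1.1e6 + 5e4, end = 1.3e6),      # 49999 gap
    dplyr::mutate(base, start = 1.3e6 + 9e4, end = 1.5e6),      # 89999 gap
    dplyr::mutate(base, start = 1.5e6 + 1.5e5 + 1, end = 1.8e6) # 150000 gap
  )
  merged <- merge_passenger_cnas(calls)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$start[1], 1e6)
  expect_equal(merged$end[1], 1.5e6)
  # idempotence
  expect_equal(merge_passenger_cnas(merged), merged)
  # permuting the input order leaves per-sample counts unchanged
  set.seed(7)
  shuffled <- calls[sample(nrow(calls)), ]
  expect_equal(nrow(merge_passenger_cnas(shuffled)), 2)
})

test_that("amplifications and deletions never merge", {
  calls <- tibble::tibble(
    sample = "s", chrom = "3",
    start = c(1e6, 1.11e6), end = c(1.1e6, 1.2e6),
    alt_type = c("deletion", "amplification"),
    role = "passenger", region_id = NA_character_
  )
  expect_equal(nrow(merge_passenger_cnas(calls)), 2)
})

test_that("satellite regions collapse onto the most-altered region", {
  regions <- tibble::tibble(
    region_id = c("r30", "r20", "r10", "other"),
    chrom = c("8", "8", "8", "9"),
    start = c(1e6, 2e6, 3e6, 1e6), end = c(1.5e6, 2.5e6, 3.5e6, 1.5e6),
    alt_type = "amplification"
  )
  M <- matrix(0, 4, 40, dimnames = list(regions$region_id, NULL))
  M["r30", 1:30] <- 1
  M["r20", 1:20] <- 1
  M["r10", 1:10] <- 1
  M["other", 31:40] <- 1
  out <- suppressMessages(
    dedupe_satellite_regions(regions, M, similarity_threshold = 0.3))
  expect_setequal(out$region_id, c("r30", "other"))
  expect_setequal(attr(out, "removed")$region_id, c("r20", "r10"))
  expect_true(all(attr(out, "removed")$kept_region == "r30"))
})

test_that("regions with dissimilar alteration patterns are all retained", {
  regions <- tibble::tibble(
    region_id = c("a", "b"), chrom = "1", start = c(1e6, 2e6),
    end = c(1.5e6, 2.5e6), alt_type = "amplification"
  )
  M <- matrix(0, 2, 20, dimnames = list(c("a", "b"), NULL))
  M["a", 1:10] <- 1
  M["b", 11:20] <- 1
  out <- dedupe_satellite_regions(regions, M, similarity_threshold = 0.6)
  expect_equal(nrow(out), 2)
  # identical patterns collapse to one
  M["b", ] <- M["a", ]
  out2 <- suppressMessages(
    dedupe_satellite_regions(regions, M, similarity_threshold = 0.6))
  expect_equal(nrow(out2), 1)
})

test_that("cohort building filters drivers by recurrence and frequency", {
  n <- 40
  ages <- tibble::tibble(sample = sprintf("s%02d", 1:n), age_years = 60)
  muts <- dplyr::bind_rows(
    tibble::tibble(sample = ages$sample[1:8], gene = "RARE",
                   is_germline = FALSE),
    tibble::tibble(sample = ages$sample[1:38], gene = "UBIQ",
                   is_germline = FALSE),
    tibble::tibble(sample = ages$sample[1:15], gene = "KEEPER",
                   is_germline = FALSE),
    tibble::tibble(sample = ages$sample, gene = "PSG", is_germline = FALSE),
    tibble::tibble(sample = "s01", gene = "GERM", is_germline = TRUE)
  )
  drivers <- c("RARE", "UBIQ", "KEEPER", "GERM")
  expect_warning(
    co <- build_cohort(muts, drivers, ages, data_kind = "mutation",
                       min_recurrence = 10),
    "near-ubiquitous"
  )
  # RARE (8 carriers) and GERM (1) drop by recurrence, UBIQ (95%) by frequency
  expect_equal(cohort_drivers(co), "KEEPER")
  # the keep-list overrides the recurrence filter
  expect_warning(
    co2 <- build_cohort(muts, drivers, ages, data_kind = "mutation",
                        min_recurrence = 10, keep = "RARE"),
    "near-ubiquitous"
  )
  expect_setequal(cohort_drivers(co2), c("RARE", "KEEPER"))
  # passenger counts exclude driver-gene and germline records
  expect_true(all(co$N == 1))
})

test_that("germline records set both indicators and recurrence sums match", {
  ages <- tibble::tibble(sample = paste0("s", 1:5), age_years = 55)
  muts <- tibble::tibble(
    sample = c("s1", "s2", "s3", "s1"),
    gene = c("BR", "BR", "BR", "BR"),
    is_germline = c(TRUE, FALSE, FALSE, FALSE)
  )
  co <- build_cohort(muts, "BR", ages, data_kind = "mutation",
                     min_recurrence = 2)
  expect_equal(co$A_BR, c(1L, 1L, 1L, 0L, 0L))
  expect_equal(co$G_BR, c(1L, 0L, 0L, 0L, 0L))
  expect_equal(sum(co$A_BR), 3)
  # dropping every driver is an error, not a silent empty cohort
  expect_error(
    suppressWarnings(build_cohort(muts[2:3, ], "BR",
                                  ages[1:3, ], data_kind = "mutation",
                                  min_recurrence = 10)),
    "no drivers retained"
  )
})

test_that("a sample without a recorded age is an error", {
  ages <- tibble::tibble(sample = "s1", age_years = 60)
  muts <- tibble::tibble(sample = c("s1", "sX"), gene = "G1",
                         is_germline = FALSE)
  expect_error(
    build_cohort(muts, "G1", ages, data_kind = "mutation", min_recurrence = 0),
    "sX"
  )
})

test_that("cohort building from CNA calls counts merged passengers", {
  regions <- tibble::tibble(
    region_id = c("amp_1", "del_1"), chrom = c("1", "2"),
    start = c(10e6, 30e6), end = c(11e6, 31e6),
    alt_type = c("amplification", "deletion")
  )
  calls <- tibble::tibble(
    sample = c("s1", "s1", "s1", "s2"),
    chrom = c("1", "5", "5", "2"),
    start = c(10e6, 1e6, 5e6, 30e6), end = c(11e6, 1.5e6, 5.5e6, 31e6),
    alt_type = c("amplification", "deletion", "deletion", "deletion"),
    role = c("driver", "passenger", "passenger", "driver"),
    region_id = c("amp_1", NA, NA, "del_1")
  )
  ages <- tibble::tibble(sample = c("s1", "s2"), age_years = c(60, 70))
  co <- build_cohort(calls, regions, ages, data_kind = "cna",
                     min_recurrence = 0)
  expect_equal(co$N, c(2L, 0L))
  expect_equal(co$A_amp_1, c(1L, 0L))
  expect_equal(co$A_del_1, c(0L, 1L))
  expect_true(all(co$G_amp_1 == 0L))
})

test_that("baseline rates follow the sequenced-length and ratio rules", {
  expect_equal(compute_lambda(3e7)$lambda_mut, 0.03)
  out <- compute_lambda(3e7, passenger_mut_mean = 8, passenger_cna_mean = 4)
  expect_equal(out$R, 0.5)
  expect_equal(out$lambda_cna, 0.015)
  expect_warning(compute_lambda(0), "degenerate")
  expect_error(compute_lambda(3e7, passenger_mut_mean = 0,
                              passenger_cna_mean = 4))
})
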