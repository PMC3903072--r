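#' Readers for the plain-text input formats
#'
#' All inputs are tab-separated text. `read_seg()` reads a SEG-like table
#' (`sample`, `chrom`, `start`, `end`, `log2_ratio`); `read_regions()` a
#' recurrent-region table (`region_id`, `chrom`, `start`, `end`,
#' `alt_type`, with `amp`/`del` accepted as shorthand); `read_mutations()`
#' a mutation table (`sample`, `gene`, `status` with values
#' `somatic`/`germline`); `read_ages()` a `sample`/`age_years` table; and
#' `read_driver_genes()` a driver gene list, one symbol per line.
#'
#' @param path File path.
#' @return A tibble (or character vector for `read_driver_genes`).
#' @name readers
NULL

.read_tsv_strict <- function(path, col_types) {
  out <- readr::read_tsv(path, col_types = col_types,
                         progress = FALSE, na = c("", "NA"))
  probs <- readr::problems(out)
  if (nrow(probs)) {
    stop("malformed row(s) in ", path, " at line(s): ",
         paste(head(unique(probs$row), 10), collapse = ", "))
  }
  out
}

#' @rdname readers
#' @export
read_seg <- function(path) {
  .read_tsv_strict(path, readr::cols(
    sample = readr::col_character(), chrom = readr::col_character(),
    start = readr::col_double(), end = readr::col_double(),
    log2_ratio = readr::col_double()
  ))
}

#' @rdname readers
#' @export
read_regions <- function(path) {
  out <- .read_tsv_strict(path, readr::cols(
    region_id = readr::col_character(), chrom = readr::col_character(),
    start = readr::col_double(), end = readr::col_double(),
    alt_type = readr::col_character()
  ))
  out$alt_type <- dplyr::recode(out$alt_type,
                                amp = "amplification", del = "deletion")
  stopifnot(all(out$alt_type %in% c("amplification", "deletion")))
  out
}

#' @rdname readers
#' @export
read_mutations <- function(path) {
  out <- .read_tsv_strict(path, readr::cols(
    sample = readr::col_character(), gene = readr::col_character(),
    status = readr::col_character()
  ))
  stopifnot(all(out$status %in% c("somatic", "germline")))
  out$is_germline <- out$status == "germline"
  out[, c("sample", "gene", "is_germline")]
}

#' @rdname readers
#' @export
read_ages <- function(path) {
  .read_tsv_strict(path, readr::cols(
    sample = readr::col_character(), age_years = readr::col_double()
  ))
}

#' @rdname readers
#' @export
read_driver_genes <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Write a cohort to a TSV file
#'
#' Columns: `sample`, `N`, `S`, then `A_<driver>` and `G_<driver>` per
#' driver. `read_cohort()` restores the `mutclock_cohort` class.
#'
#' @param cohort A `mutclock_cohort`.
#' @param path File path.
#' @param data_kind Data kind to assume when reading back.
#' @return `write_cohort` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(as.data.frame(cohort), path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, data_kind = c("mutation", "cna")) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_cohort(out, data_kind = match.arg(data_kind))
}
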