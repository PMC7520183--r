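#' Read a prey read-count table
#'
#' Reads a delimited table of metabarcoding read counts with one row per scat
#' sample and one column per prey taxon. The first column must be the sample
#' identifier; all remaining columns are taxa. Counts must be non-negative
#' integers; a taxon never detected in a sample is a zero count, not a
#' missing value.
#'
#' @param path Path to a CSV file with a header row of taxon names.
#' @return A tibble with a `sample_id` character column followed by one
#'   integer column per taxon.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,herring,hake", "s1,10,0", "s2,3,7"), tf)
#' read_count_table(tf)
read_count_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 2) abort("count table needs a sample_id column and at least one taxon column")
  names(raw)[1] <- "sample_id"
  taxa <- names(raw)[-1]
  if (anyDuplicated(taxa)) {
    abort(paste0("duplicate taxon columns: ",
                 paste(unique(taxa[duplicated(taxa)]), collapse = ", ")))
  }
  if (anyDuplicated(raw$sample_id)) {
    abort(paste0("duplicate sample_id: ",
                 paste(unique(raw$sample_id[duplicated(raw$sample_id)]), collapse = ", ")))
  }
  counts <- raw
  for (tx in taxa) {
    v <- suppressWarnings(as.numeric(raw[[tx]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      abort(sprintf(
        "invalid count '%s' at sample '%s', taxon '%s': counts must be non-negative integers",
        raw[[tx]][bad[1]], raw$sample_id[bad[1]], tx
      ))
    }
    counts[[tx]] <- as.integer(v)
  }
  zero <- rowSums(as.matrix(counts[taxa])) == 0
  if (any(zero)) {
    abort(paste0("sample(s) with no positive counts: ",
                 paste(counts$sample_id[zero], collapse = ", ")))
  }
  counts
}

#' Write a prey read-count table
#'
#' Inverse of [read_count_table()]: `read_count_table(write_count_table(x, f))`
#' returns `x` for any well-formed table.
#'
#' @param counts A count tibble as returned by [read_count_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  readr::write_csv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path CSV with columns `sample_id`, `location`, `month`, `year`.
#'   Months may be numbers (1-12) or English names/abbreviations.
#' @return Tibble with `sample_id`, `location` (character), `month`
#'   (integer 1-12) and `year` (integer).
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "location", "month", "year")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    abort(paste0("metadata is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(meta[need])) abort("metadata must have non-missing sample_id, location, month, year")
  dplyr::mutate(
    meta,
    sample_id = as.character(.data$sample_id),
    location = as.character(.data$location),
    month = month_to_int(.data$month),
    year = as.integer(.data$year)
  )
}

#' Read replicated qPCR sexing calls
#'
#' @param path CSV with columns `sample_id`, `zfx_1`, `zfx_2`, `zfy_1`,
#'   `zfy_2`; amplification coded 0/1 (or logical). A failed reaction is
#'   "not amplified" (0), never missing.
#' @return Tibble with logical amplification columns.
#' @export
read_qpcr_table <- function(path) {
  q <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "zfx_1", "zfx_2", "zfy_1", "zfy_2")
  missing_cols <- setdiff(need, names(q))
  if (length(missing_cols)) {
    abort(paste0("qPCR table is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (col in need[-1]) {
    v <- q[[col]]
    if (is.logical(v)) next
    if (!all(v %in% c(0, 1))) {
      abort(paste0("qPCR column ", col, " must be 0/1 or logical with no missing values"))
    }
    q[[col]] <- v == 1
  }
  if (anyNA(q[need])) abort("qPCR amplification calls must not be missing")
  dplyr::mutate(q, sample_id = as.character(.data$sample_id))
}

#' Read a taxon annotation table
#'
#' Maps species-level taxa to taxonomic orders, habitat classes and salmonid
#' status, used for order lumping, benthic diet fractions and the
#' juvenile/adult salmon split.
#'
#' @param path CSV with columns `taxon`, `order`, `habitat`
#'   (benthic/demersal/pelagic/unknown), `is_salmonid`, `species`. If `NULL`,
#'   the packaged illustrative annotation for common Salish Sea prey is
#'   returned (a constructed starter table, not a curated authority).
#' @return Tibble of annotations.
#' @export
read_taxon_annotation <- function(path = NULL) {
  if (is.null(path)) path <- dietspec_extdata("prey_annotation_illustrative.csv")
  ann <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("taxon", "order", "habitat", "is_salmonid")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols)) {
    abort(paste0("annotation is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  ok <- c("benthic", "demersal", "pelagic", "unknown")
  bad <- setdiff(unique(ann$habitat), ok)
  if (length(bad)) {
    abort(paste0("unknown habitat class(es): ", paste(bad, collapse = ", ")))
  }
  ann$is_salmonid <- as.logical(ann$is_salmonid)
  ann
}

#' Read a hard-part juvenile/adult salmon ratio table
#'
#' @param path CSV with columns `scope` (sample/month/season), `sample_id`,
#'   `location`, `year`, `month`, `season`, `species`, `juvenile_fraction`.
#'   Key columns not applying to a scope are left empty.
#' @return Tibble of ratios; `juvenile_fraction` validated to `[0, 1]`.
#' @export
read_hardpart_table <- function(path) {
  hp <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("scope", "species", "juvenile_fraction")
  missing_cols <- setdiff(need, names(hp))
  if (length(missing_cols)) {
    abort(paste0("hard-part table is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(!hp$scope %in% c("sample", "month", "season"))) {
    abort("hard-part scope must be one of sample, month, season")
  }
  if (any(hp$juvenile_fraction < 0 | hp$juvenile_fraction > 1)) {
    abort("juvenile_fraction must lie in [0, 1]")
  }
  for (col in c("sample_id", "location", "season")) {
    if (!col %in% names(hp)) hp[[col]] <- NA_character_
  }
  for (col in c("year", "month")) {
    if (!col %in% names(hp)) hp[[col]] <- NA_integer_
  }
  hp
}

#' Packaged harbor-seal group summary table
#'
#' The published per-group summary of the Salish Sea harbor seal scat study
#' the package reproduces: one row per Location x Sex x Year x Month group
#' with its minimum prey density, theoretical minimum PSi (1/N), sample size,
#' mean PSi, retention flag and Shannon-Weaver index. Values are stored
#' exactly as printed; see the methods vignette for known internal
#' inconsistencies of the source table.
#'
#' @return Tibble with 111 rows and columns `location`, `month` (integer),
#'   `month_label`, `year`, `season`, `sex`, `min_prey_density`,
#'   `theoretical_min`, `n`, `mean_psi`, `retained` (logical), `shannon`.
#' @export
#' @examples
#' hs_group_summary() |> dplyr::filter(retained) |> nrow()
hs_group_summary <- function() {
  t1 <- readr::read_csv(dietspec_extdata("table1_groups.csv"),
                        show_col_types = FALSE, progress = FALSE)
  tibble::tibble(
    location = t1$location,
    month = month_to_int(t1$month),
    month_label = .month_levels[month_to_int(t1$month)],
    year = as.integer(t1$year),
    season = tolower(t1$season),
    sex = t1$sex,
    min_prey_density = t1$min_prey_density,
    theoretical_min = t1$theoretical_min,
    n = as.integer(t1$n),
    mean_psi = t1$mean_psi,
    retained = t1$use == "Yes",
    shannon = t1$shannon
  )
}

#' Packaged monthly sexed-scat counts
#'
#' Counts of successfully sexed scats by location, year, month and sex from
#' the same study, stored per cell; the printed row and column totals are
#' recovered by summation (grand total 1,145).
#'
#' @return Tibble with columns `location`, `environment`, `year`, `month`
#'   (integer), `month_label`, `n_female`, `n_male`.
#' @export
hs_sexing_counts <- function() {
  t2 <- readr::read_csv(dietspec_extdata("table2_sexed_counts.csv"),
                        show_col_types = FALSE, progress = FALSE)
  dplyr::mutate(
    t2,
    month_label = .data$month,
    month = month_to_int(.data$month),
    year = as.integer(.data$year)
  )
}

#' Packaged mixed-model comparison table
#'
#' The study's four-model comparison of logit(PSi) mixed models: fixed-effect
#' structure, marginal and conditional r-squared, AIC and Akaike weight,
#' sorted by AIC.
#'
#' @return Tibble with columns `predictors`, `r2_fixed`, `r2`, `aic`, `wi`.
#' @export
hs_model_comparison <- function() {
  readr::read_csv(dietspec_extdata("table3_models.csv"),
                  show_col_types = FALSE, progress = FALSE)
}
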