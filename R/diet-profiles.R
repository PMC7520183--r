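#' Convert read counts to per-sample diet proportions
#'
#' Each sample's prey read counts are closed to proportions
#' (count / total reads for that sample). Taxa with zero reads in a sample
#' are dropped from the long output; they are implicit zeros and are
#' restored wherever a common resource axis is needed.
#'
#' @param counts Wide count tibble (`sample_id` + one integer column per
#'   taxon), e.g. from [read_count_table()] or [simulate_study()].
#' @return Long tibble with columns `sample_id`, `taxon`, `proportion`;
#'   proportions sum to 1 within each sample.
#' @export
#' @examples
#' tibble::tibble(sample_id = "s1", herring = 10L, hake = 30L, sole = 60L) |>
#'   diet_proportions()
diet_proportions <- function(counts) {
  if (!"sample_id" %in% names(counts)) abort("counts must have a sample_id column")
  long <- tidyr::pivot_longer(counts, -"sample_id",
                              names_to = "taxon", values_to = "count")
  if (any(long$count < 0)) abort("read counts must be non-negative")
  long <- dplyr::group_by(long, .data$sample_id)
  totals <- dplyr::summarise(long, total = sum(.data$count))
  if (any(totals$total == 0)) {
    abort(paste0("sample(s) with zero total reads: ",
                 paste(totals$sample_id[totals$total == 0], collapse = ", ")))
  }
  long |>
    dplyr::mutate(proportion = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$proportion > 0) |>
    dplyr::select("sample_id", "taxon", "proportion")
}

#' Lump species-level diet proportions into taxonomic orders
#'
#' Sums proportions of member species within each order; compositional
#' closure is conserved (each sample still sums to 1).
#'
#' @param props Long proportion tibble from [diet_proportions()].
#' @param annotation Taxon annotation from [read_taxon_annotation()].
#' @return Long tibble with columns `sample_id`, `order`, `proportion`.
#' @export
aggregate_orders <- function(props, annotation = read_taxon_annotation()) {
  unknown <- setdiff(unique(props$taxon), annotation$taxon)
  if (length(unknown)) {
    abort(paste0("taxa with nonzero proportion but no annotation: ",
                 paste(unknown, collapse = ", ")))
  }
  props |>
    dplyr::inner_join(annotation[c("taxon", "order")], by = "taxon") |>
    dplyr::group_by(.data$sample_id, .data$order) |>
    dplyr::summarise(proportion = sum(.data$proportion), .groups = "drop")
}

#' Look up the juvenile fraction of a salmonid species for one sample
#'
#' Hard-part analysis yields juvenile-versus-adult ratios at three scopes.
#' The most specific available is used: the sample itself, then the
#' collection month (within location and year), then the season (within
#' location and year, falling back to a global season entry), and finally
#' an all-adult default of 0.
#'
#' @param hardpart Ratio table from [read_hardpart_table()] (may have 0 rows).
#' @param species Salmonid taxon id.
#' @param sample_id,location,year,month Keys of the sample.
#' @return A list with `juvenile_fraction` and `scope`
#'   (one of `"sample"`, `"month"`, `"season"`, `"default-adult"`).
#' @export
lookup_juvenile_ratio <- function(hardpart, species, sample_id = NA,
                                  location = NA, year = NA, month = NA) {
  hp <- hardpart[hardpart$species == species, , drop = FALSE]
  pick <- function(rows, scope) list(juvenile_fraction = rows$juvenile_fraction[1], scope = scope)
  s <- hp[hp$scope == "sample" & !is.na(hp$sample_id) & hp$sample_id == sample_id, , drop = FALSE]
  if (nrow(s)) return(pick(s, "sample"))
  m <- hp[hp$scope == "month" & !is.na(hp$month) & hp$month == month_to_int(month) &
            !is.na(hp$location) & hp$location == location &
            !is.na(hp$year) & hp$year == year, , drop = FALSE]
  if (nrow(m)) return(pick(m, "month"))
  season <- if (!is.na(month)) season_of(month) else NA_character_
  se <- hp[hp$scope == "season" & !is.na(hp$season) & hp$season == season &
             !is.na(hp$location) & hp$location == location &
             !is.na(hp$year) & hp$year == year, , drop = FALSE]
  if (nrow(se)) return(pick(se, "season"))
  sg <- hp[hp$scope == "season" & !is.na(hp$season) & hp$season == season &
             is.na(hp$location), , drop = FALSE]
  if (nrow(sg)) return(pick(sg, "season"))
  list(juvenile_fraction = 0, scope = "default-adult")
}

#' Split salmonid diet proportions into juvenile and adult pseudo-orders
#'
#' The DNA proportion of each salmonid species in each sample is divided
#' into a juvenile and an adult share by the hard-part juvenile ratio for
#' that sample (see [lookup_juvenile_ratio()]), then summed across salmonid
#' species into the pseudo-orders `"Juvenile Salmoniformes"` and
#' `"Adult Salmoniformes"`. These rows are *added* to the order-level
#' profile; the Salmoniformes order row is retained, and the two shares sum
#' to it exactly.
#'
#' @param order_props Order-level proportions from [aggregate_orders()].
#' @param props Species-level proportions from [diet_proportions()].
#' @param annotation Taxon annotation (salmonid flags).
#' @param metadata Sample metadata (for month-/season-scope lookups);
#'   optional when `hardpart` is empty.
#' @param hardpart Hard-part ratio table; `NULL` means no hard-part data
#'   (every ratio falls through to the all-adult default).
#' @param pooled If `TRUE`, apply one pooled ratio (per sample) to the summed
#'   Salmoniformes proportion instead of splitting per species.
#' @return `order_props` with the two pseudo-order rows appended (samples
#'   with no salmonid reads get none).
#' @export
split_salmonids <- function(order_props, props, annotation = read_taxon_annotation(),
                            metadata = NULL, hardpart = NULL, pooled = FALSE) {
  if (is.null(hardpart)) {
    hardpart <- tibble::tibble(scope = character(), sample_id = character(),
                               location = character(), year = integer(),
                               month = integer(), season = character(),
                               species = character(), juvenile_fraction = double())
  }
  salmonids <- annotation$taxon[annotation$is_salmonid]
  sp <- props[props$taxon %in% salmonids, , drop = FALSE]
  if (nrow(sp) == 0) return(order_props)
  if (pooled) {
    sp <- sp |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(proportion = sum(.data$proportion), .groups = "drop") |>
      dplyr::mutate(taxon = "Salmoniformes")
  }
  meta_of <- function(id) {
    if (is.null(metadata)) return(list(location = NA, year = NA, month = NA))
    row <- metadata[metadata$sample_id == id, , drop = FALSE]
    if (nrow(row) == 0) return(list(location = NA, year = NA, month = NA))
    list(location = row$location[1], year = row$year[1], month = row$month[1])
  }
  split_rows <- purrr::pmap(sp, function(sample_id, taxon, proportion, ...) {
    md <- meta_of(sample_id)
    r <- lookup_juvenile_ratio(hardpart, species = taxon, sample_id = sample_id,
                               location = md$location, year = md$year, month = md$month)
    tibble::tibble(
      sample_id = sample_id,
      order = c("Juvenile Salmoniformes", "Adult Salmoniformes"),
      proportion = c(proportion * r$juvenile_fraction,
                     proportion * (1 - r$juvenile_fraction))
    )
  })
  pseudo <- dplyr::bind_rows(split_rows) |>
    dplyr::group_by(.data$sample_id, .data$order) |>
    dplyr::summarise(proportion = sum(.data$proportion), .groups = "drop")
  dplyr::bind_rows(order_props, pseudo)
}

#' Benthic fraction of each sample's diet
#'
#' Sums the proportions of taxa annotated as benthic. Taxa with an unknown
#' habitat class contribute zero; their total share per call is reported
#' with a warning so silent coverage gaps are visible.
#'
#' @param props Species-level proportions from [diet_proportions()].
#' @param annotation Taxon annotation with a `habitat` column.
#' @return Tibble with `sample_id` and `benthic_fraction` in `[0, 1]`
#'   (samples with no benthic taxa get 0).
#' @export
benthic_fraction <- function(props, annotation = read_taxon_annotation()) {
  joined <- dplyr::left_join(props, annotation[c("taxon", "habitat")], by = "taxon")
  joined$habitat[is.na(joined$habitat)] <- "unknown"
  unk <- sum(joined$proportion[joined$habitat == "unknown"])
  if (unk > 0) {
    warn(sprintf("%.4f total proportion carries an unknown habitat class and counts as non-benthic", unk))
  }
  joined |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      benthic_fraction = sum(.data$proportion[.data$habitat == "benthic"]),
      .groups = "drop"
    )
}
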