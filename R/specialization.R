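#' Proportional similarity between an individual and its population diet
#'
#' The proportional similarity index
#' `PSi = 1 - 0.5 * sum_j |p_j - q_j|` measures the overlap between an
#' individual's diet proportions `p` and the population's `q`. A value of 1
#' is a perfect generalist (identical to the population diet); the
#' population-dependent minimum (1/N in an N-member group where the rarest
#' resource can be monopolised) marks a complete specialist.
#'
#' @param p,q Proportion vectors, each summing to 1 (tolerance 1e-9). Named
#'   vectors are aligned on the union of their names (absent resources are
#'   zeros); unnamed vectors must have equal length and are matched
#'   positionally.
#' @return A single value in `[0, 1]`.
#' @export
#' @examples
#' psi(c(a = 0.5, b = 0.5), c(a = 0.25, b = 0.25, c = 0.5))
psi <- function(p, q) {
  if (is.null(names(p)) != is.null(names(q))) {
    abort("p and q must both be named or both unnamed")
  }
  if (is.null(names(p))) {
    if (length(p) != length(q)) abort("unnamed p and q must have equal length")
  } else {
    taxa <- union(names(p), names(q))
    p <- ifelse(is.na(p[taxa]), 0, p[taxa])
    q <- ifelse(is.na(q[taxa]), 0, q[taxa])
  }
  if (any(p < 0) || any(q < 0)) abort("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    abort("p and q must each sum to 1 (within 1e-9)")
  }
  1 - 0.5 * sum(abs(p - q))
}

#' Population diet of a set of samples
#'
#' The population's use of resource j is the unweighted mean of the member
#' diet proportion vectors over the union of their taxa (each scat carries
#' equal weight regardless of read depth). Under this convention a sole
#' specialist on an otherwise untouched resource attains PSi exactly 1/N.
#'
#' @param props Long proportion tibble (`sample_id`, `taxon`, `proportion`)
#'   for the member samples.
#' @return Named numeric vector `q` over the union of taxa, summing to 1.
#' @export
population_diet <- function(props) {
  if (nrow(props) == 0) abort("cannot compute a population diet from zero samples")
  n <- dplyr::n_distinct(props$sample_id)
  q <- tapply(props$proportion, props$taxon, sum) / n
  q <- q[order(names(q))]
  setNames(as.numeric(q), names(q))
}

#' Bin sexed samples into location-sex-year-month groups
#'
#' Samples with an excluded sex call are dropped; the remainder are
#' partitioned by Location, Sex, Year and Month. The partition is exhaustive
#' and disjoint: group sizes sum to the number of sexed samples.
#'
#' @param samples Tibble with `sample_id`, `location`, `month`, `year` and a
#'   `sex_call` (or `sex`) column.
#' @return The sexed samples with `sex`, `season` and `group_id` columns.
#' @export
form_groups <- function(samples) {
  if (!"sex_call" %in% names(samples) && "sex" %in% names(samples)) {
    samples$sex_call <- tolower(as.character(samples$sex))
  }
  need <- c("sample_id", "location", "month", "year", "sex_call")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols)) {
    abort(paste0("samples are missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(samples[c("location", "month", "year")])) {
    abort("grouping metadata (location, month, year) must be complete")
  }
  samples |>
    dplyr::filter(.data$sex_call %in% c("male", "female")) |>
    dplyr::mutate(
      sex = as.character(.data$sex_call),
      month = month_to_int(.data$month),
      season = season_of(.data$month),
      group_id = paste(.data$location, .data$sex, .data$year, .data$month, sep = "_")
    )
}

#' Per-sample PSi within each group
#'
#' Computes each sample's PSi against its group's population diet on the
#' species-level resource axis (the union of taxa observed in the group).
#' Single-member groups are assigned PSi 1 by the self-comparison convention
#' and flagged; they are removed by the standard N >= 5 retention filter
#' before any inference.
#'
#' @param props Long proportion tibble from [diet_proportions()].
#' @param groups Grouped sample table from [form_groups()].
#' @return Tibble with one row per sexed sample: metadata, `group_id`,
#'   `group_n`, `psi` and `logit_psi` (see [logit()] for the clamping
#'   policy near 1).
#' @export
group_psi <- function(props, groups) {
  missing_props <- setdiff(groups$sample_id, unique(props$sample_id))
  if (length(missing_props)) {
    abort(paste0("samples without diet proportions: ",
                 paste(head(missing_props, 5), collapse = ", ")))
  }
  merged <- dplyr::inner_join(
    props, groups[c("sample_id", "location", "sex", "year", "month", "season", "group_id")],
    by = "sample_id"
  )
  per_group <- merged |>
    dplyr::group_by(.data$group_id) |>
    dplyr::group_map(function(g, key) {
      ids <- unique(g$sample_id)
      q <- population_diet(g)
      psis <- vapply(ids, function(id) {
        p_i <- setNames(g$proportion[g$sample_id == id], g$taxon[g$sample_id == id])
        p_full <- setNames(numeric(length(q)), names(q))
        p_full[names(p_i)] <- p_i
        psi(p_full, q)
      }, numeric(1))
      if (length(ids) == 1) psis[] <- 1  # degenerate self-comparison convention
      tibble::tibble(group_id = key$group_id, sample_id = ids,
                     group_n = length(ids), psi = unname(psis))
    }) |>
    dplyr::bind_rows()
  groups |>
    dplyr::select("sample_id", "location", "sex", "year", "month", "season") |>
    dplyr::inner_join(per_group, by = "sample_id") |>
    dplyr::mutate(logit_psi = logit(.data$psi))
}

#' Summarize groups in the study's per-group layout
#'
#' One row per group: sample size, theoretical minimum PSi (1/N), minimum
#' prey density (smallest nonzero proportion in any member scat), mean PSi,
#' Shannon-Weaver diversity of the averaged group diet (in nats, via
#' [vegan::diversity()]), season, and the retention flag at `min_n`.
#'
#' @param props Long proportion tibble.
#' @param groups Grouped sample table from [form_groups()].
#' @param min_n Minimum group size for retention (default 5).
#' @return Tibble with columns `group_id`, `location`, `sex`, `year`,
#'   `month`, `season`, `min_prey_density`, `theoretical_min`, `n`,
#'   `mean_psi`, `retained`, `shannon`.
#' @export
summarize_groups <- function(props, groups, min_n = 5) {
  samp <- group_psi(props, groups)
  merged <- dplyr::inner_join(
    props, groups[c("sample_id", "group_id")], by = "sample_id"
  )
  diet_stats <- merged |>
    dplyr::group_by(.data$group_id) |>
    dplyr::group_map(function(g, key) {
      q <- population_diet(g)
      tibble::tibble(
        group_id = key$group_id,
        min_prey_density = min(g$proportion),
        shannon = as.numeric(vegan::diversity(q, index = "shannon"))
      )
    }) |>
    dplyr::bind_rows()
  samp |>
    dplyr::group_by(.data$group_id, .data$location, .data$sex, .data$year,
                    .data$month, .data$season) |>
    dplyr::summarise(n = dplyr::n(), mean_psi = mean(.data$psi), .groups = "drop") |>
    dplyr::left_join(diet_stats, by = "group_id") |>
    dplyr::mutate(theoretical_min = theoretical_minimum(.data$n)) |>
    filter_groups(min_n = min_n) |>
    dplyr::select("group_id", "location", "sex", "year", "month", "season",
                  "min_prey_density", "theoretical_min", "n", "mean_psi",
                  "retained", "shannon")
}

#' Flag groups retained under a minimum-size filter
#'
#' Groups smaller than `min_n` have the highest theoretical minima and the
#' greatest sample-size bias; they are flagged rather than deleted.
#'
#' @param group_summary Tibble with an `n` column.
#' @param min_n Minimum size (default 5); a group is retained iff `n >= min_n`.
#' @return The input with a logical `retained` column (replaced if present).
#' @export
filter_groups <- function(group_summary, min_n = 5) {
  dplyr::mutate(group_summary, retained = .data$n >= min_n)
}

#' Theoretical minimum PSi of an N-member group
#'
#' @param n Integer group size(s), `>= 1`.
#' @return `1/n`.
#' @export
theoretical_minimum <- function(n) {
  if (any(n < 1 | n != round(n))) abort("group size must be a positive integer")
  1 / n
}

#' Shannon-Weaver diversity of a diet vector
#'
#' `H = -sum_j q_j ln q_j` in nats, with `0 ln 0 = 0`, computed with
#' [vegan::diversity()] on the averaged group diet.
#'
#' @param q Proportion vector summing to 1.
#' @return Diversity in nats.
#' @export
shannon_index <- function(q) {
  if (abs(sum(q) - 1) > 1e-9) abort("q must sum to 1")
  as.numeric(vegan::diversity(q, index = "shannon"))
}

#' Logit transform with a boundary clamping policy
#'
#' `logit(x) = ln(x / (1 - x))`, used to open up the doubly-bounded PSi
#' scale before mixed modelling. Exact 1 (identical diets) is clamped to
#' `1 - clamp` and exact 0 to `clamp`, each with a warning; in retained
#' groups PSi = 0 cannot occur because every sample contributes to its own
#' population diet.
#'
#' @param x Values in `[0, 1]`.
#' @param clamp Boundary offset (default `1e-6`).
#' @return `ln(x / (1 - x))` after clamping.
#' @export
logit <- function(x, clamp = 1e-6) {
  hi <- x >= 1
  lo <- x <= 0
  if (any(hi | lo, na.rm = TRUE)) {
    warn(sprintf("%d value(s) at the boundary clamped to [%g, %g] before logit",
                 sum(hi | lo, na.rm = TRUE), clamp, 1 - clamp))
    x[hi] <- 1 - clamp
    x[lo] <- clamp
  }
  log(x / (1 - x))
}

#' Season of a collection month
#'
#' Spring is April-May, summer June-August, fall September-November; months
#' outside the April-November study window are labelled `"out-of-window"`.
#'
#' @param month Month number (1-12) or name.
#' @return Character vector of seasons.
#' @export
season_of <- function(month) {
  m <- month_to_int(month)
  dplyr::case_when(
    m %in% 4:5 ~ "spring",
    m %in% 6:8 ~ "summer",
    m %in% 9:11 ~ "fall",
    TRUE ~ "out-of-window"
  )
}

#' Percentile bootstrap confidence interval of a mean
#'
#' Monte Carlo resampling with replacement; the interval is reported both as
#' percentile bounds and as a single half-width `(upper - lower) / 2`,
#' matching the "95% CI = x" reporting style for bounded indices.
#'
#' @param values Numeric vector, length >= 2.
#' @param R Number of resamples (>= 1000; default 100,000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed for reproducibility (the global RNG
#'   state is left untouched).
#' @return One-row tibble: `mean`, `lower`, `upper`, `half_width`, `R`.
#' @export
bootstrap_mean_ci <- function(values, R = 100000, conf = 0.95, seed = NULL) {
  if (length(values) < 2) abort("need at least 2 values to bootstrap")
  if (R < 1000) abort("R must be at least 1000")
  run <- function() {
    n <- length(values)
    means <- numeric(R)
    # chunked so R * n never materialises at once
    chunk <- max(1L, floor(5e6 / n))
    done <- 0L
    while (done < R) {
      k <- min(chunk, R - done)
      m <- matrix(sample(values, n * k, replace = TRUE), nrow = n)
      means[(done + 1L):(done + k)] <- colMeans(m)
      done <- done + k
    }
    means
  }
  means <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  alpha <- (1 - conf) / 2
  qs <- unname(stats::quantile(means, c(alpha, 1 - alpha), type = 7))
  tibble::tibble(
    mean = mean(values), lower = qs[1], upper = qs[2],
    half_width = (qs[2] - qs[1]) / 2, R = R
  )
}

#' Moment skewness and kurtosis
#'
#' Moment estimators: skewness `g1 = m3 / m2^1.5` and kurtosis
#' `m4 / m2^2`, reported non-excess (a normal distribution has kurtosis 3);
#' set `excess = TRUE` to subtract 3.
#'
#' @param values Numeric vector, length >= 3 with positive variance.
#' @param excess Report excess kurtosis? Default `FALSE`.
#' @return One-row tibble with `skewness` and `kurtosis`.
#' @export
moment_stats <- function(values, excess = FALSE) {
  if (length(values) < 3) abort("need at least 3 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) abort("zero variance: moments undefined")
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  tibble::tibble(
    skewness = m3 / m2^1.5,
    kurtosis = m4 / m2^2 - if (excess) 3 else 0
  )
}

#' Sample-weighted mean PSi over retained groups
#'
#' `sum(N_g * meanPSi_g) / sum(N_g)`, identical to the mean over individual
#' samples when group means are exact.
#'
#' @param group_summary Group table with `n`, `mean_psi` and (optionally)
#'   `retained`; non-retained rows are excluded when the flag is present.
#' @return A single value.
#' @export
weighted_mean_psi <- function(group_summary) {
  if ("retained" %in% names(group_summary)) {
    group_summary <- group_summary[group_summary$retained, , drop = FALSE]
  }
  if (nrow(group_summary) == 0) abort("no retained groups")
  sum(group_summary$n * group_summary$mean_psi) / sum(group_summary$n)
}
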