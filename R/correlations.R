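#' Spearman rank correlation with tie-aware p-values
#'
#' rho is the Pearson correlation of mid-ranks (ties averaged). The
#' two-sided p-value uses the exact permutation distribution (exhaustive
#' enumeration, valid under ties) for n <= 8 and the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be constant.
#' @return One-row tibble with `rho`, `p_value`, `n`, `method`.
#' @export
#' @examples
#' spearman_cor(1:6, c(2, 1, 4, 3, 6, 5))
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("rho is undefined for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- all_permutations(n)
    # correlation of rx with every permutation of ry, vectorised
    rx_c <- rx - mean(rx)
    ry_mat <- matrix(ry[perms], nrow = nrow(perms))
    num <- as.numeric(ry_mat %*% rx_c)
    denom <- sqrt(sum(rx_c^2)) * sqrt(sum((ry - mean(ry))^2))
    rho_perm <- num / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  tibble::tibble(rho = rho, p_value = min(p, 1), n = n, method = method)
}

# all n! permutations of 1:n as an n! x n matrix (n <= 8)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    remap <- setdiff(seq_len(n), i)
    out[rows, -1L] <- matrix(remap[sub], nrow(sub))
  }
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param base_alpha Family-wise alpha (default 0.05).
#' @param n_tests Number of tests (>= 1).
#' @return `base_alpha / n_tests`, rounded to 4 decimals as reported.
#' @export
#' @examples
#' bonferroni_alpha(0.05, 13)
bonferroni_alpha <- function(base_alpha = 0.05, n_tests) {
  if (n_tests < 1) abort("n_tests must be at least 1")
  round(base_alpha / n_tests, 4)
}

#' Correlations between prey-order proportions and PSi
#'
#' For each order (including the juvenile/adult Salmoniformes
#' pseudo-orders), the Spearman correlation between the proportion of the
#' diet that order makes up in each sample and that sample's PSi, over all
#' samples of the subset (zeros included). A negative rho associates the
#' order with specialization, because small PSi means a specialised diet.
#' The Bonferroni threshold divides alpha by the number of *base* orders;
#' pseudo-orders inherit the same threshold.
#'
#' @param psi_tbl Per-sample PSi tibble from [group_psi()]; only retained
#'   samples should be supplied (filter on group size first).
#' @param order_props Long order-level proportions
#'   (from [aggregate_orders()] / [split_salmonids()]).
#' @param subset `"all"`, `"female"` or `"male"`.
#' @param base_alpha Family-wise alpha (default 0.05).
#' @param n_tests Number of tests for the Bonferroni divisor; defaults to
#'   the number of base orders (pseudo-orders excluded).
#' @return Tibble with one row per order: `order`, `subset`, `rho`,
#'   `p_value`, `n`, `occurrences` (samples with proportion > 0), `alpha`,
#'   `significant`. Orders that are absent or constant within the subset
#'   are skipped with a warning.
#' @export
order_psi_correlations <- function(psi_tbl, order_props,
                                   subset = c("all", "female", "male"),
                                   base_alpha = 0.05, n_tests = NULL) {
  subset <- match.arg(subset)
  if (subset != "all") psi_tbl <- psi_tbl[psi_tbl$sex == subset, , drop = FALSE]
  if (nrow(psi_tbl) == 0) abort("no samples in the requested subset")
  orders <- sort(unique(order_props$order))
  pseudo <- c("Juvenile Salmoniformes", "Adult Salmoniformes")
  if (is.null(n_tests)) n_tests <- length(setdiff(orders, pseudo))
  alpha <- bonferroni_alpha(base_alpha, n_tests)
  wide <- order_props |>
    dplyr::filter(.data$sample_id %in% psi_tbl$sample_id) |>
    tidyr::pivot_wider(id_cols = "sample_id", names_from = "order",
                       values_from = "proportion", values_fill = 0)
  merged <- dplyr::inner_join(psi_tbl[c("sample_id", "psi")], wide, by = "sample_id")
  rows <- purrr::map(orders, function(ord) {
    v <- merged[[ord]] %||% rep(0, nrow(merged))
    if (length(unique(v)) == 1) {
      warn(paste0("order '", ord, "' is constant in subset '", subset, "'; skipped"))
      return(NULL)
    }
    sc <- spearman_cor(v, merged$psi)
    tibble::tibble(
      order = ord, subset = subset, rho = sc$rho, p_value = sc$p_value,
      n = sc$n, occurrences = sum(v > 0), alpha = alpha,
      significant = sc$p_value < alpha
    )
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$rho)
}

#' Sample-size bias diagnostic for group mean PSi
#'
#' Spearman correlation between each retained group's mean PSi and its
#' sample size N. Because the theoretical minimum is 1/N, a correlation
#' with N is the exact negative of a correlation with the theoretical
#' minimum; the sample-size orientation is reported, so a negative rho
#' means larger groups score lower mean PSi.
#'
#' @param group_summary Group table with `mean_psi`, `n` and optionally
#'   `retained` (non-retained rows are dropped when present).
#' @return One-row tibble with `rho`, `p_value`, `n_groups`.
#' @export
sample_size_bias <- function(group_summary) {
  if ("retained" %in% names(group_summary)) {
    group_summary <- group_summary[group_summary$retained, , drop = FALSE]
  }
  if (nrow(group_summary) < 3) abort("need at least 3 retained groups")
  sc <- spearman_cor(group_summary$mean_psi, group_summary$n)
  tibble::tibble(rho = sc$rho, p_value = sc$p_value, n_groups = nrow(group_summary))
}

#' Sex-ratio versus specialization across paired groups
#'
#' Male and female groups sharing a location, month and year are paired.
#' Each pair's sex ratio is the percent of its scats identified as female;
#' its mean PSi is the sample-weighted mean over the two groups. The two
#' are compared with a Spearman correlation.
#'
#' @param group_summary Group table from [summarize_groups()].
#' @param require_retained If `TRUE` (default) both groups of a pair must be
#'   retained.
#' @return List with `pairs` (tibble: location, month, year,
#'   `percent_female`, `mean_psi`, `n_total`) and `correlation`
#'   (one-row tibble `rho`, `p_value`, `n_pairs`).
#' @export
sex_ratio_analysis <- function(group_summary, require_retained = TRUE) {
  g <- group_summary
  g$sex <- tolower(as.character(g$sex))
  if (require_retained && "retained" %in% names(g)) {
    g <- g[g$retained, , drop = FALSE]
  }
  pairs <- g |>
    dplyr::group_by(.data$location, .data$month, .data$year) |>
    dplyr::filter(dplyr::n_distinct(.data$sex) == 2) |>
    dplyr::summarise(
      percent_female = sum(.data$n[.data$sex == "female"]) / sum(.data$n),
      mean_psi = sum(.data$n * .data$mean_psi) / sum(.data$n),
      n_total = sum(.data$n),
      .groups = "drop"
    )
  if (nrow(pairs) == 0) abort("no male/female group pairs to analyse")
  sc <- spearman_cor(pairs$percent_female, pairs$mean_psi)
  list(
    pairs = pairs,
    correlation = tibble::tibble(rho = sc$rho, p_value = sc$p_value,
                                 n_pairs = nrow(pairs))
  )
}
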