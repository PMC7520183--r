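#' Call depositor sex from replicated ZFX/ZFY qPCR amplification
#'
#' Each scat is assayed in duplicate with a ZFX probe (amplifies in both
#' sexes) and a ZFY probe (Y chromosome only). A sample is called male if any
#' ZFX reaction and any ZFY reaction amplified; female if any ZFX amplified
#' but neither ZFY did. Samples with no ZFX amplification are excluded:
#' `excluded_no_zfx` when ZFY also failed, `excluded_zfy_only` when a ZFY
#' reaction amplified without ZFX support. The four rules partition all 16
#' amplification patterns.
#'
#' @param qpcr Tibble with logical (or 0/1) columns `zfx_1`, `zfx_2`,
#'   `zfy_1`, `zfy_2`, e.g. from [read_qpcr_table()].
#' @return The input with a `sex_call` factor column with levels
#'   `male`, `female`, `excluded_no_zfx`, `excluded_zfy_only`.
#' @export
#' @examples
#' tibble::tibble(sample_id = c("a", "b", "c"),
#'                zfx_1 = c(TRUE, TRUE, FALSE), zfx_2 = c(FALSE, TRUE, FALSE),
#'                zfy_1 = c(TRUE, FALSE, TRUE), zfy_2 = c(FALSE, FALSE, FALSE)) |>
#'   call_sex()
call_sex <- function(qpcr) {
  need <- c("zfx_1", "zfx_2", "zfy_1", "zfy_2")
  missing_cols <- setdiff(need, names(qpcr))
  if (length(missing_cols)) {
    abort(paste0("qPCR data is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(qpcr[need])) abort("amplification calls must not be missing (a failed reaction is FALSE)")
  zfx <- as.logical(qpcr$zfx_1) | as.logical(qpcr$zfx_2)
  zfy <- as.logical(qpcr$zfy_1) | as.logical(qpcr$zfy_2)
  call <- dplyr::case_when(
    zfx & zfy ~ "male",
    zfx & !zfy ~ "female",
    !zfx & !zfy ~ "excluded_no_zfx",
    TRUE ~ "excluded_zfy_only"
  )
  dplyr::mutate(qpcr, sex_call = factor(call, levels = sex_call_levels()))
}

sex_call_levels <- function() {
  c("male", "female", "excluded_no_zfx", "excluded_zfy_only")
}

#' Summarize sexing outcomes
#'
#' @param qpcr Tibble of qPCR records; [call_sex()] is applied if a
#'   `sex_call` column is not already present.
#' @return One-row tibble with counts per call and `success_rate`
#'   (sexed / total, as a proportion).
#' @export
summarize_sexing <- function(qpcr) {
  if (nrow(qpcr) == 0) abort("no qPCR records to summarize")
  if (!"sex_call" %in% names(qpcr)) qpcr <- call_sex(qpcr)
  tab <- table(factor(qpcr$sex_call, levels = sex_call_levels()))
  tibble::tibble(
    n_total = nrow(qpcr),
    n_male = unname(tab["male"]),
    n_female = unname(tab["female"]),
    n_excluded_no_zfx = unname(tab["excluded_no_zfx"]),
    n_excluded_zfy_only = unname(tab["excluded_zfy_only"]),
    success_rate = unname(tab["male"] + tab["female"]) / nrow(qpcr)
  )
}

#' Estimate the male-to-female false-negative rate of the ZFY assay
#'
#' A male is misclassified as female only when both ZFY reactions fail. The
#' per-reaction dropout probability q is estimated from males (samples with
#' at least one positive ZFY reaction) via the observed fraction f with
#' exactly one positive ZFY. Conditional on classification as male,
#' f = 2q(1-q) / (1-q^2) = 2q / (1+q), inverted as q = f / (2-f); the
#' two-reaction false-negative rate is q^2. The `unconditional` method
#' instead treats f as the unconditional single-dropout probability
#' 2q(1-q) and solves the quadratic.
#'
#' @param qpcr Tibble of qPCR records; sex calls are computed if absent.
#' @param method `"conditional"` (default) or `"unconditional"`.
#' @return One-row tibble with `n_male`, `f_single_dropout`, `q_hat`
#'   (per-reaction dropout) and `false_negative_rate` (= `q_hat^2`).
#' @export
estimate_false_negative_rate <- function(qpcr, method = c("conditional", "unconditional")) {
  method <- match.arg(method)
  if (!"sex_call" %in% names(qpcr)) qpcr <- call_sex(qpcr)
  males <- qpcr[qpcr$sex_call == "male", , drop = FALSE]
  if (nrow(males) == 0) abort("no male-classified records: dropout rate is inestimable")
  n_pos <- as.integer(males$zfy_1) + as.integer(males$zfy_2)
  f <- mean(n_pos == 1)
  if (f >= 1) abort("all males show single ZFY dropout: estimator undefined at f = 1")
  q_hat <- switch(method,
    conditional = f / (2 - f),
    unconditional = {
      if (f > 0.5) abort("unconditional inversion requires f <= 0.5")
      (1 - sqrt(1 - 2 * f)) / 2
    }
  )
  tibble::tibble(
    method = method,
    n_male = nrow(males),
    f_single_dropout = f,
    q_hat = q_hat,
    false_negative_rate = q_hat^2
  )
}
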