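#' The standard model family for logit(PSi)
#'
#' Four fixed-effect structures over Sex and Month (categorical), each with
#' random intercepts for Sample Size, Location and Year: the Sex-by-Month
#' interaction model, the additive model, Month only, and Sex only.
#'
#' @return Named list of one-sided fixed-effect formulas.
#' @export
standard_model_set <- function() {
  list(
    "Sex*Month" = ~ sex * month,
    "Sex + Month" = ~ sex + month,
    "Month" = ~ month,
    "Sex" = ~ sex
  )
}

#' Fit a linear mixed model of logit-transformed PSi
#'
#' REML fit (via [lme4::lmer()]) of `logit_psi` on categorical fixed
#' effects with random intercepts for sample size (each distinct group size
#' is one level, shared by all samples in groups of that size), location and
#' year. The AIC follows the REML convention
#' `-2 logLik + 2k`, `k` = fixed coefficients + variance components +
#' residual. A variance component estimated at zero yields a singular-fit
#' warning, not an error.
#'
#' @param data Per-sample tibble with `logit_psi`, `sex`, `month`,
#'   `group_n`, `location`, `year` (e.g. from [group_psi()]).
#' @param fixed One-sided formula of fixed effects over `sex` and `month`
#'   (default `~ sex * month`).
#' @param label Optional model label for reporting.
#' @return An object of class `psi_lmm`; see [tidy.psi_lmm()] and
#'   [glance.psi_lmm()].
#' @export
fit_psi_lmm <- function(data, fixed = ~ sex * month, label = NULL) {
  need <- c("logit_psi", "sex", "month", "group_n", "location", "year")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("model data is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  d <- data |>
    dplyr::transmute(
      logit_psi = .data$logit_psi,
      sex = factor(.data$sex),
      month = factor(.data$month),
      sample_size = factor(.data$group_n),
      location = factor(.data$location),
      year = factor(.data$year)
    )
  fixed_terms <- attr(stats::terms(fixed), "term.labels")
  ran <- c("sample_size", "location", "year")
  estimable <- vapply(ran, function(v) nlevels(d[[v]]) > 1, logical(1))
  if (!all(estimable)) {
    warn(paste0("random intercept(s) dropped (single level): ",
                paste(ran[!estimable], collapse = ", ")))
  }
  ran <- ran[estimable]
  if (!length(ran)) abort("no random-intercept factor has more than one level")
  rhs <- paste(c(if (length(fixed_terms)) fixed_terms else "1",
                 sprintf("(1 | %s)", ran)),
               collapse = " + ")
  form <- stats::as.formula(paste("logit_psi ~", rhs))
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  if (lme4::isSingular(fit)) {
    warn("singular fit: at least one variance component is estimated at zero")
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- tibble::tibble(
    component = ifelse(vc$grp == "Residual", "residual", vc$grp),
    variance = vc$vcov,
    sd = vc$sdcor
  )
  r2 <- r2_mixed_components(fit)
  structure(
    list(
      fit = fit,
      label = label %||% deparse(fixed),
      fixed = fixed,
      aic = as.numeric(stats::AIC(fit)),
      log_lik = as.numeric(stats::logLik(fit)),
      n_param = attr(stats::logLik(fit), "df"),
      varcomp = comp,
      r2_marginal = r2$r2_marginal,
      r2_conditional = r2$r2_conditional,
      nobs = nrow(d)
    ),
    class = "psi_lmm"
  )
}

#' @export
print.psi_lmm <- function(x, ...) {
  cat("Mixed model of logit(PSi):", x$label, "\n")
  cat(sprintf("  n = %d, AIC = %.2f, r2 marginal = %.3f, conditional = %.3f\n",
              x$nobs, x$aic, x$r2_marginal, x$r2_conditional))
  cat("  variance components:\n")
  for (i in seq_len(nrow(x$varcomp))) {
    cat(sprintf("    %-12s var = %.4f (SD = %.4f)\n",
                x$varcomp$component[i], x$varcomp$variance[i], x$varcomp$sd[i]))
  }
  invisible(x)
}

r2_mixed_components <- function(fit) {
  var_fixed <- stats::var(as.numeric(stats::predict(fit, re.form = NA)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_random <- sum(vc$vcov[vc$grp != "Residual"])
  var_resid <- vc$vcov[vc$grp == "Residual"]
  denom <- var_fixed + var_random + var_resid
  list(
    r2_marginal = var_fixed / denom,
    r2_conditional = (var_fixed + var_random) / denom
  )
}

#' Variance explained by fixed and random effects of a mixed model
#'
#' Variance-component r-squared for Gaussian mixed models: the marginal
#' value is `var(fixed fitted values)` over the total of fixed, random and
#' residual variances; the conditional value adds the random components to
#' the numerator.
#'
#' @param fit A `psi_lmm` object or a fitted [lme4::lmer()] model.
#' @return One-row tibble with `r2_marginal` and `r2_conditional`.
#' @export
r2_mixed <- function(fit) {
  if (inherits(fit, "psi_lmm")) fit <- fit$fit
  tibble::as_tibble(r2_mixed_components(fit))
}

#' Akaike weights of a model set
#'
#' `w_i = exp(-dAIC_i / 2) / sum_k exp(-dAIC_k / 2)` with
#' `dAIC_i = AIC_i - min(AIC)`; weights are invariant to shifting all AICs
#' by a constant and sum to 1.
#'
#' @param aic Numeric vector of AIC values (length >= 2).
#' @return Numeric vector of weights, same order as `aic`.
#' @export
#' @examples
#' akaike_weights(c(3141.78, 3157.91, 3172.53, 3191.43))
akaike_weights <- function(aic) {
  if (length(aic) < 2) abort("need at least two AIC values")
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Fit and compare the standard model family
#'
#' Fits each fixed-effect structure with the shared random-intercept set and
#' tabulates AIC, delta-AIC, Akaike weight and marginal/conditional
#' r-squared, sorted by AIC.
#'
#' @param data Per-sample tibble as for [fit_psi_lmm()].
#' @param models Named list of fixed-effect formulas
#'   (default [standard_model_set()]).
#' @return Tibble with one row per model (`predictors`, `r2_fixed`, `r2`,
#'   `aic`, `delta_aic`, `wi`) and the fitted `psi_lmm` objects in a
#'   list-column `fit`.
#' @export
compare_psi_models <- function(data, models = standard_model_set()) {
  fits <- purrr::imap(models, function(f, nm) {
    tryCatch(
      fit_psi_lmm(data, fixed = f, label = nm),
      error = function(e) abort(paste0("model '", nm, "' failed to fit: ", conditionMessage(e)))
    )
  })
  out <- tibble::tibble(
    predictors = names(fits),
    r2_fixed = unname(purrr::map_dbl(fits, "r2_marginal")),
    r2 = unname(purrr::map_dbl(fits, "r2_conditional")),
    aic = unname(purrr::map_dbl(fits, "aic")),
    fit = unname(fits)
  )
  out$wi <- akaike_weights(out$aic)
  out |>
    dplyr::arrange(.data$aic) |>
    dplyr::mutate(delta_aic = .data$aic - min(.data$aic)) |>
    dplyr::select("predictors", "r2_fixed", "r2", "aic", "delta_aic", "wi", "fit")
}

#' Tidy a fitted PSi mixed model
#'
#' @param x A `psi_lmm` object.
#' @param effects `"fixed"` for fixed-effect coefficients with t statistics,
#'   `"ran_pars"` for variance components.
#' @param ... Unused.
#' @return A tibble in broom layout.
#' @export
tidy.psi_lmm <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    co <- summary(x$fit)$coefficients
    tibble::tibble(
      effect = "fixed",
      term = rownames(co),
      estimate = co[, "Estimate"],
      std.error = co[, "Std. Error"],
      statistic = co[, "t value"]
    )
  } else {
    dplyr::mutate(x$varcomp, effect = "ran_pars", .before = 1)
  }
}

#' One-row summary of a fitted PSi mixed model
#'
#' @param x A `psi_lmm` object.
#' @param ... Unused.
#' @return Tibble with `nobs`, `logLik`, `AIC`, `df`, `sigma`,
#'   `r2_marginal`, `r2_conditional`.
#' @export
glance.psi_lmm <- function(x, ...) {
  tibble::tibble(
    nobs = x$nobs,
    logLik = x$log_lik,
    AIC = x$aic,
    df = x$n_param,
    sigma = stats::sigma(x$fit),
    r2_marginal = x$r2_marginal,
    r2_conditional = x$r2_conditional
  )
}
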