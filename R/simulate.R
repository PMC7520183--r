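#' Configuration for a synthetic scat-metabarcoding study
#'
#' Describes the generative model used throughout the test-suite: per group a
#' base diet `q0 ~ Dirichlet(alpha0)` over the annotated taxa; individual
#' diets `p_i ~ Dirichlet(c * q0)` where the concentration `c` (per sex) is
#' the single specialization knob — small `c` gives individuals far from the
#' group diet (specialists), large `c` generalists; read counts
#' `~ Multinomial(depth_i, p_i)` with lognormal depths floored at
#' `depth_min`; qPCR records drawn from the true sex with a sample-level
#' extraction failure rate and independent per-reaction dropout
#' probabilities.
#'
#' The default group template (keys and sample sizes) mirrors the packaged
#' harbor-seal group summary, so the simulated study has the same
#' location-sex-year-month structure and sexed sample sizes as the study
#' being reproduced; default dropout rates reproduce its 75% sexing success
#' and ~1.35% two-reaction ZFY false-negative rate, and the default
#' concentrations put simulated mean PSi near the observed ~0.4.
#'
#' @param seed Integer seed; all randomness in [simulate_study()] derives
#'   from it.
#' @param template Tibble with `location`, `sex`, `year`, `month`, `n`
#'   (target sexed samples per group). Default: retained and unretained
#'   rows of [hs_group_summary()].
#' @param annotation Taxon annotation tibble; default the packaged
#'   illustrative annotation.
#' @param alpha0 Per-taxon Dirichlet concentration of group base diets
#'   (> 0; small values give sparse, zero-rich diets).
#' @param concentration Named vector `c(female = ..., male = ...)` of
#'   individual-diet concentrations (> 0).
#' @param depth_meanlog,depth_sdlog,depth_min Read-depth distribution
#'   (rounded lognormal, floored).
#' @param extraction_failure Probability a sample yields no amplifiable DNA
#'   (all four reactions fail).
#' @param zfx_dropout,zfy_dropout Per-reaction dropout probabilities in
#'   `[0, 0.5)`.
#' @param juvenile_shape1,juvenile_shape2 Beta parameters of the
#'   month-scope juvenile salmon fractions.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed = 1,
                              template = NULL,
                              annotation = NULL,
                              alpha0 = 0.35,
                              concentration = c(female = 2, male = 4),
                              depth_meanlog = log(2000),
                              depth_sdlog = 0.7,
                              depth_min = 100,
                              extraction_failure = 0.25,
                              zfx_dropout = 0.05,
                              zfy_dropout = 0.116,
                              juvenile_shape1 = 2,
                              juvenile_shape2 = 2) {
  if (is.null(template)) {
    g <- hs_group_summary()
    template <- tibble::tibble(location = g$location, sex = tolower(g$sex),
                               year = g$year, month = g$month, n = g$n)
  }
  if (is.null(annotation)) annotation <- read_taxon_annotation()
  stopifnot(all(c("location", "sex", "year", "month", "n") %in% names(template)))
  if (alpha0 <= 0) abort("alpha0 must be positive")
  if (any(concentration <= 0)) abort("concentrations must be positive")
  if (!all(c("female", "male") %in% names(concentration))) {
    abort("concentration must be named with 'female' and 'male'")
  }
  for (q in c(extraction_failure, zfx_dropout, zfy_dropout)) {
    if (q < 0 || q >= 0.5) abort("failure/dropout rates must lie in [0, 0.5)")
  }
  if (depth_min < 1) abort("depth_min must be >= 1")
  if (any(template$n < 1)) abort("template group sizes must be >= 1")
  structure(
    list(seed = as.integer(seed), template = template, annotation = annotation,
         alpha0 = alpha0, concentration = concentration,
         depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
         depth_min = depth_min, extraction_failure = extraction_failure,
         zfx_dropout = zfx_dropout, zfy_dropout = zfy_dropout,
         juvenile_shape1 = juvenile_shape1, juvenile_shape2 = juvenile_shape2),
    class = "sim_config"
  )
}

# n draws from Dirichlet(alpha) as an n x K matrix
rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  # a whole row can underflow to 0 for very sparse alpha; redraw those rows
  zero <- rowSums(x) == 0
  while (any(zero)) {
    x[zero, ] <- matrix(rgamma(sum(zero) * k, shape = rep(alpha, each = sum(zero))),
                        nrow = sum(zero))
    zero <- rowSums(x) == 0
  }
  x / rowSums(x)
}

#' Simulate one group of scat samples
#'
#' Draws `n` individual diets from `Dirichlet(c * q0)` and a multinomial
#' read-count vector for each at a lognormal depth. Uses the current RNG
#' state; seed externally (e.g. [withr::with_seed()]) for reproducibility.
#'
#' @param q0 Base (population) diet, summing to 1; names become taxon names.
#' @param c_conc Individual-diet concentration (> 0).
#' @param n Number of samples.
#' @param depth_meanlog,depth_sdlog,depth_min Read-depth distribution.
#' @return Integer count matrix (`n` rows, `length(q0)` columns).
#' @export
simulate_group <- function(q0, c_conc, n, depth_meanlog = log(2000),
                           depth_sdlog = 0.7, depth_min = 100) {
  if (abs(sum(q0) - 1) > 1e-9) abort("q0 must sum to 1")
  if (c_conc <= 0) abort("concentration must be positive")
  p <- rdirichlet_mat(n, c_conc * q0)
  depth <- pmax(depth_min, round(rlnorm(n, depth_meanlog, depth_sdlog)))
  counts <- t(vapply(seq_len(n),
                     function(i) as.integer(rmultinom(1, depth[i], p[i, ])),
                     integer(length(q0))))
  colnames(counts) <- names(q0)
  counts
}

#' Simulate a complete synthetic study
#'
#' Generates, per template group, enough collected scats that the expected
#' number surviving sexing equals the template size, then draws diets, read
#' counts, qPCR records and month-scope hard-part juvenile ratios. The
#' returned truth record stores every generative parameter (and each
#' sample's true sex and concentration) so recovery tests never reverse
#' engineer truth from outputs. The whole dataset feeds the pipeline
#' unmodified.
#'
#' @param config A [simulation_config()].
#' @return List with `counts` (wide tibble), `metadata`, `qpcr`, `hardpart`,
#'   `annotation` and `truth` (list: `params` key-value vector, `samples`
#'   tibble).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(config) {
  ann <- config$annotation
  taxa <- ann$taxon
  k <- length(taxa)
  p_success <- (1 - config$extraction_failure) * (1 - config$zfx_dropout^2)
  tpl <- config$template
  all_counts <- list(); all_meta <- list(); all_qpcr <- list(); all_truth <- list()
  sample_counter <- 0L
  for (i in seq_len(nrow(tpl))) {
    n_collect <- max(1L, as.integer(round(tpl$n[i] / p_success)))
    q0 <- as.numeric(rdirichlet_mat(1, rep(config$alpha0, k)))
    names(q0) <- taxa
    c_conc <- config$concentration[[tolower(tpl$sex[i])]]
    counts <- simulate_group(q0, c_conc, n_collect, config$depth_meanlog,
                             config$depth_sdlog, config$depth_min)
    ids <- sprintf("S%05d", sample_counter + seq_len(n_collect))
    sample_counter <- sample_counter + n_collect
    extraction_ok <- rbinom(n_collect, 1, 1 - config$extraction_failure) == 1
    amp <- function(dropout) extraction_ok & (rbinom(n_collect, 1, 1 - dropout) == 1)
    is_male <- tolower(tpl$sex[i]) == "male"
    qpcr <- tibble::tibble(
      sample_id = ids,
      zfx_1 = amp(config$zfx_dropout),
      zfx_2 = amp(config$zfx_dropout),
      zfy_1 = if (is_male) amp(config$zfy_dropout) else FALSE,
      zfy_2 = if (is_male) amp(config$zfy_dropout) else FALSE
    )
    all_counts[[i]] <- tibble::as_tibble(cbind(tibble::tibble(sample_id = ids),
                                               tibble::as_tibble(counts)))
    all_meta[[i]] <- tibble::tibble(sample_id = ids, location = tpl$location[i],
                                    month = tpl$month[i], year = tpl$year[i])
    all_qpcr[[i]] <- qpcr
    all_truth[[i]] <- tibble::tibble(
      sample_id = ids, location = tpl$location[i], month = tpl$month[i],
      year = tpl$year[i], true_sex = tolower(tpl$sex[i]),
      concentration = c_conc, template_n = tpl$n[i]
    )
  }
  salmonids <- ann$taxon[ann$is_salmonid]
  hp_keys <- unique(tpl[c("location", "year", "month")])
  hardpart <- tidyr::expand_grid(hp_keys, species = salmonids) |>
    dplyr::mutate(
      scope = "month",
      sample_id = NA_character_,
      season = NA_character_,
      juvenile_fraction = stats::rbeta(dplyr::n(), config$juvenile_shape1,
                                       config$juvenile_shape2)
    )
  params <- c(
    seed = config$seed, alpha0 = config$alpha0,
    c_female = config$concentration[["female"]],
    c_male = config$concentration[["male"]],
    depth_meanlog = config$depth_meanlog, depth_sdlog = config$depth_sdlog,
    depth_min = config$depth_min, extraction_failure = config$extraction_failure,
    zfx_dropout = config$zfx_dropout, zfy_dropout = config$zfy_dropout,
    juvenile_shape1 = config$juvenile_shape1,
    juvenile_shape2 = config$juvenile_shape2
  )
  list(
    counts = dplyr::bind_rows(all_counts),
    metadata = dplyr::bind_rows(all_meta),
    qpcr = dplyr::bind_rows(all_qpcr),
    hardpart = hardpart,
    annotation = ann,
    truth = list(params = params, samples = dplyr::bind_rows(all_truth))
  )
}

#' Save / load a simulation truth record
#'
#' The truth record is written as two plain-text files in `dir`:
#' `truth_params.txt` (one `key: value` line per generative parameter) and
#' `truth_samples.csv` (per-sample true sex and concentration).
#' `read_truth_record(write_truth_record(truth, dir))` round-trips.
#'
#' @param truth The `truth` element of [simulate_study()] output.
#' @param dir Directory (created if needed).
#' @return `dir` invisibly (write); a truth list (read).
#' @export
write_truth_record <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(paste0(names(truth$params), ": ",
                    formatC(truth$params, format = "g", digits = 17)),
             file.path(dir, "truth_params.txt"))
  readr::write_csv(truth$samples, file.path(dir, "truth_samples.csv"), progress = FALSE)
  invisible(dir)
}

#' @rdname write_truth_record
#' @export
read_truth_record <- function(dir) {
  lines <- readLines(file.path(dir, "truth_params.txt"))
  kv <- strsplit(lines, ": ", fixed = TRUE)
  params <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                     vapply(kv, `[`, "", 1))
  samples <- readr::read_csv(file.path(dir, "truth_samples.csv"),
                             show_col_types = FALSE, progress = FALSE)
  list(params = params, samples = samples)
}

#' Monte Carlo oracle for the expected group mean PSi
#'
#' Repeatedly simulates a fresh group under the Dirichlet-multinomial model
#' and computes its mean PSi through the package's own proportion and PSi
#' machinery, averaging over replicates. Used to verify that mean PSi is
#' monotone in the concentration `c` (more concentrated individuals are
#' less specialised).
#'
#' @param q0 Base diet (sums to 1).
#' @param c_conc Individual-diet concentration.
#' @param n Group size.
#' @param reps Number of replicate groups (>= 1000 for stable estimates).
#' @param seed Integer seed.
#' @param depth_meanlog,depth_sdlog,depth_min Read-depth distribution.
#' @return One-row tibble: `expected_mean_psi`, `mc_se`, `reps`.
#' @export
expected_psi_oracle <- function(q0, c_conc, n, reps = 2000, seed = 1,
                                depth_meanlog = log(2000), depth_sdlog = 0.7,
                                depth_min = 100) {
  vals <- withr::with_seed(seed, vapply(seq_len(reps), function(r) {
    if (n == 1) return(1)  # degenerate self-comparison convention
    counts <- simulate_group(q0, c_conc, n, depth_meanlog, depth_sdlog, depth_min)
    props <- counts / rowSums(counts)
    q <- colMeans(props)
    mean(vapply(seq_len(n), function(i) psi(props[i, ], q), numeric(1)))
  }, numeric(1)))
  tibble::tibble(expected_mean_psi = mean(vals),
                 mc_se = stats::sd(vals) / sqrt(reps), reps = reps)
}
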