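test_that("psi matches the overlap formula and its min-sum identity", {
  expect_equal(psi(c(0.3, 0.7), c(0.3, 0.7)), 1)
  expect_equal(psi(c(a = 1), c(b = 1)), 0)
  expect_equal(psi(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)), 0.5)
  expect_error(psi(c(0.5, 0.6), c(0.5, 0.5)), "sum to 1")
  expect_error(psi(c(0.5, 0.5), c(0.25, 0.25, 0.5)), "equal length")

  # named vectors align on the union of taxa
  expect_equal(psi(c(a = 0.5, b = 0.5), c(a = 0.25, b = 0.25, c = 0.5)), 0.5)

  # independent identity: 1 - 0.5*sum|p-q| == sum(pmin(p, q)) on the union
  withr::with_seed(11, {
    for (i in 1:50) {
      k <- sample(2:8, 1)
      p <- as.numeric(dietspec:::rdirichlet_mat(1, rep(0.5, k)))
      q <- as.numeric(dietspec:::rdirichlet_mat(1, rep(0.5, k)))
      expect_equal(psi(p, q), sum(pmin(p, q)), tolerance = 1e-12)
    }
  })
})

test_that("population diet is the unweighted member mean over the taxon union", {
  single <- props_from_list(list(s1 = c(a = 0.2, b = 0.8)))
  expect_equal(population_diet(single), c(a = 0.2, b = 0.8))

  two <- props_from_list(list(s1 = c(a = 1), s2 = c(b = 1)))
  expect_equal(population_diet(two), c(a = 0.5, b = 0.5))

  # sole specialist's taxon gets q = 1/N
  n <- 5
  diets <- c(list(spec = c(x = 1)),
             purrr::map(setNames(1:(n - 1), paste0("g", 1:(n - 1))),
                        ~ c(a = 0.5, b = 0.5)))
  q <- population_diet(props_from_list(diets))
  expect_equal(unname(q["x"]), 1 / n)
  expect_error(population_diet(props_from_list(list())), "zero samples")
})

test_that("group formation partitions sexed samples by location-sex-year-month", {
  s <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    location = c("A", "A", "B", "B", "A", "B"),
    month = 6, year = 2012,
    sex_call = c("male", "female", "male", "female", "male", "excluded_no_zfx")
  )
  g <- form_groups(s)
  expect_equal(nrow(g), 5)  # excluded dropped
  expect_equal(dplyr::n_distinct(g$group_id), 4)
  expect_equal(sort(table(g$group_id), decreasing = TRUE)[[1]], 2)  # A male x2

  same <- tibble::tibble(sample_id = paste0("s", 1:4), location = "A",
                         month = 5, year = 2012, sex_call = "female")
  expect_equal(dplyr::n_distinct(form_groups(same)$group_id), 1)

  # partition property: group sizes sum to the sexed-sample count
  expect_equal(sum(table(g$group_id)), sum(s$sex_call %in% c("male", "female")))
})

test_that("a sole specialist attains PSi exactly 1/N", {
  n <- 5
  diets <- c(list(spec = c(x = 1)),
             purrr::map(setNames(1:(n - 1), paste0("g", 1:(n - 1))),
                        ~ c(a = 0.5, b = 0.5)))
  props <- props_from_list(diets)
  groups <- one_group(names(diets))
  res <- group_psi(props, groups)
  expect_equal(res$psi[res$sample_id == "spec"], 1 / n, tolerance = 1e-12)
  expect_true(all(res$psi >= 1 / n - 1e-12))
})

test_that("identical diets give PSi 1 in every member and matching diversity", {
  diets <- purrr::map(setNames(1:4, paste0("s", 1:4)),
                      ~ c(a = 0.5, b = 0.25, c = 0.25))
  props <- props_from_list(diets)
  groups <- one_group(names(diets))
  expect_warning(res <- group_psi(props, groups), "clamped")
  expect_equal(res$psi, rep(1, 4))
  q <- population_diet(props)
  expect_equal(shannon_index(q), shannon_index(c(a = 0.5, b = 0.25, c = 0.25)))
})

test_that("theoretical minimum is the reciprocal group size", {
  expect_equal(theoretical_minimum(5), 0.2)
  expect_lt(abs(theoretical_minimum(37) - 0.027), 5e-5)
  expect_equal(theoretical_minimum(1), 1)
  expect_error(theoretical_minimum(0), "positive integer")
})

test_that("group summaries report minima, diversity and retention", {
  diets <- list(s1 = c(a = 0.99, b = 0.01), s2 = c(a = 0.998, b = 0.002))
  props <- props_from_list(diets)
  groups <- one_group(names(diets))
  gs <- summarize_groups(props, groups, min_n = 5)
  expect_equal(gs$min_prey_density, 0.002)
  expect_equal(gs$theoretical_min, 0.5)
  expect_false(gs$retained)

  # single member eating a single taxon
  props1 <- props_from_list(list(s1 = c(a = 1)))
  gs1 <- suppressWarnings(summarize_groups(props1, one_group("s1"), min_n = 5))
  expect_equal(gs1$min_prey_density, 1)
  expect_equal(gs1$mean_psi, 1)  # degenerate self-comparison convention
  expect_equal(gs1$shannon, 0)

  # retention boundary: N = 4 excluded, N = 5 retained
  flags <- filter_groups(tibble::tibble(n = c(4, 5)), min_n = 5)
  expect_equal(flags$retained, c(FALSE, TRUE))
})

test_that("shannon index matches the entropy formula in nats", {
  expect_equal(shannon_index(c(one = 1)), 0)
  expect_equal(shannon_index(rep(0.25, 4)), log(4))
  q <- c(0.5, 0.25, 0.25)
  expect_equal(shannon_index(q), 1.0397, tolerance = 1e-4)
  expect_equal(shannon_index(q), -sum(q * log(q)), tolerance = 1e-12)
})

test_that("logit transform is antisymmetric and clamps boundaries", {
  expect_equal(logit(0.5), 0)
  expect_lt(abs(logit(0.399) - (-0.4097)), 1e-4)
  x <- c(0.1, 0.25, 0.6, 0.93)
  expect_equal(logit(x), -logit(1 - x), tolerance = 1e-12)
  expect_warning(v <- logit(1), "clamped")
  expect_equal(v, log((1 - 1e-6) / 1e-6))
  expect_warning(logit(0), "clamped")
})

test_that("season mapping follows the study's month bins", {
  expect_equal(season_of(5), "spring")
  expect_equal(season_of("May"), "spring")
  expect_equal(season_of(8), "summer")
  expect_equal(season_of("August"), "summer")
  expect_equal(season_of(11), "fall")
  expect_equal(season_of("November"), "fall")
  expect_equal(season_of(1), "out-of-window")
})

test_that("bootstrap CI is deterministic under a seed and degenerate on constants", {
  const <- rep(0.4, 10)
  ci <- bootstrap_mean_ci(const, R = 1000, seed = 1)
  expect_equal(ci$half_width, 0)

  x <- withr::with_seed(5, rnorm(200))
  ci1 <- bootstrap_mean_ci(x, R = 2000, seed = 9)
  ci2 <- bootstrap_mean_ci(x, R = 2000, seed = 9)
  expect_equal(ci1, ci2)
  ci3 <- bootstrap_mean_ci(x, R = 2000, seed = 10)
  expect_false(identical(ci1$lower, ci3$lower))

  expect_error(bootstrap_mean_ci(1, R = 1000), "at least 2")
  expect_error(bootstrap_mean_ci(x, R = 10), "at least 1000")
})

test_that("bootstrap half-width tracks the CLT closed form", {
  x <- withr::with_seed(21, rnorm(1000))
  ci <- bootstrap_mean_ci(x, R = 20000, seed = 2)
  clt <- 1.96 * sd(x) / sqrt(1000)
  expect_lt(abs(ci$half_width - clt) / clt, 0.15)
})

test_that("moment statistics match an independent oracle", {
  skip_if_not_installed("e1071")
  x <- withr::with_seed(31, rnorm(20))
  ms <- moment_stats(x)
  expect_equal(ms$skewness, e1071::skewness(x, type = 1), tolerance = 1e-12)
  expect_equal(ms$kurtosis, e1071::kurtosis(x, type = 1) + 3, tolerance = 1e-12)
  expect_equal(moment_stats(x, excess = TRUE)$kurtosis, ms$kurtosis - 3)

  sym <- c(-3, -1, 0, 1, 3)
  expect_equal(moment_stats(sym)$skewness, 0)

  big <- withr::with_seed(32, rnorm(2e5))
  expect_equal(moment_stats(big)$kurtosis, 3, tolerance = 0.05)
  expect_error(moment_stats(rep(1, 5)), "zero variance")
})

test_that("weighted mean PSi weights groups by their sample sizes", {
  one <- tibble::tibble(n = 7, mean_psi = 0.42)
  expect_equal(weighted_mean_psi(one), 0.42)
  two <- tibble::tibble(n = c(2, 8), mean_psi = c(0.4, 0.6))
  expect_equal(weighted_mean_psi(two), 0.56)
  flagged <- tibble::tibble(n = c(2, 8), mean_psi = c(0.4, 0.6),
                            retained = c(FALSE, TRUE))
  expect_equal(weighted_mean_psi(flagged), 0.6)
})

test_that("PSi respects the group lower bound across random simulated groups", {
  withr::with_seed(77, {
    for (i in 1:10) {
      n <- sample(3:12, 1)
      k <- sample(4:12, 1)
      counts <- simulate_group(setNames(rep(1 / k, k), paste0("t", 1:k)),
                               c_conc = runif(1, 0.5, 20), n = n)
      counts_tbl <- tibble::as_tibble(counts) |>
        dplyr::mutate(sample_id = paste0("s", seq_len(n)), .before = 1)
      props <- diet_proportions(counts_tbl)
      res <- group_psi(props, one_group(counts_tbl$sample_id))
      expect_true(all(res$psi >= 1 / n - 1e-12))
      expect_true(all(res$psi <= 1 + 1e-12))
    }
  })
})
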