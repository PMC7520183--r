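# in-code fixtures shared across test files

toy_counts <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    herring = c(10L, 0L, 1L),
    hake = c(30L, 5L, 1L),
    sole = c(60L, 0L, 1L),
    squid = c(0L, 5L, 1L)
  )
}

toy_annotation <- function() {
  tibble::tibble(
    taxon = c("herring", "hake", "sole", "squid", "chinook", "coho"),
    order = c("Clupeiformes", "Gadiformes", "Pleuronectiformes", "Cephalopoda",
              "Salmoniformes", "Salmoniformes"),
    habitat = c("pelagic", "demersal", "benthic", "pelagic", "pelagic", "pelagic"),
    is_salmonid = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    species = c("herring", "hake", "sole", "squid", "chinook", "coho")
  )
}

# long proportions for a hand-built group; `diets` is a named list of named
# proportion vectors keyed by sample id
props_from_list <- function(diets) {
  purrr::imap_dfr(diets, function(p, id) {
    tibble::tibble(sample_id = id, taxon = names(p), proportion = unname(p))
  })
}

# minimal grouped-sample table for one group
one_group <- function(ids, sex = "female", location = "L1", year = 2012, month = 6) {
  tibble::tibble(
    sample_id = ids, location = location, month = month, year = year,
    sex_call = sex
  ) |> dietspec::form_groups()
}

# simulated per-sample model data with known generative structure
simulate_lmm_data <- function(n, sd_location = 0, sd_year = 0, sd_size = 0,
                              sd_resid = 1, beta_sex = 0, beta_month = NULL,
                              beta_inter = NULL, n_month = 6, n_location = 5,
                              n_year = 4, n_size = 8) {
  month <- sample.int(n_month, n, replace = TRUE)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  location <- paste0("L", sample.int(n_location, n, replace = TRUE))
  year <- (2011 + seq_len(n_year))[sample.int(n_year, n, replace = TRUE)]
  size <- (4 + seq_len(n_size))[sample.int(n_size, n, replace = TRUE)]
  if (is.null(beta_month)) beta_month <- rep(0, n_month)
  if (is.null(beta_inter)) beta_inter <- rep(0, n_month)
  u_loc <- stats::rnorm(n_location, 0, sd_location)
  u_year <- stats::rnorm(n_year, 0, sd_year)
  u_size <- stats::rnorm(n_size, 0, sd_size)
  y <- beta_sex * (sex == "male") + beta_month[month] +
    beta_inter[month] * (sex == "male") +
    u_loc[match(location, paste0("L", seq_len(n_location)))] +
    u_year[match(year, 2011 + seq_len(n_year))] +
    u_size[match(size, 4 + seq_len(n_size))] +
    stats::rnorm(n, 0, sd_resid)
  tibble::tibble(
    logit_psi = y, sex = sex, month = month, group_n = size,
    location = location, year = year
  )
}

# qPCR record builder: each row from a TRUE male with per-reaction ZFY dropout q
simulate_male_qpcr <- function(n, q_zfy, q_zfx = 0) {
  tibble::tibble(
    sample_id = sprintf("m%06d", seq_len(n)),
    zfx_1 = stats::rbinom(n, 1, 1 - q_zfx) == 1,
    zfx_2 = stats::rbinom(n, 1, 1 - q_zfx) == 1,
    zfy_1 = stats::rbinom(n, 1, 1 - q_zfy) == 1,
    zfy_2 = stats::rbinom(n, 1, 1 - q_zfy) == 1
  )
}
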