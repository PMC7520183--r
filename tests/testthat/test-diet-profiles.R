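test_that("read counts close to proportions within each sample", {
  p <- diet_proportions(tibble::tibble(sample_id = "s1", a = 10L, b = 30L, c = 60L))
  expect_equal(p$proportion, c(0.1, 0.3, 0.6))

  p1 <- diet_proportions(tibble::tibble(sample_id = "s1", only = 5L))
  expect_equal(p1$proportion, 1)

  p4 <- diet_proportions(tibble::tibble(sample_id = "s1", a = 1L, b = 1L, c = 1L, d = 1L))
  expect_equal(p4$proportion, rep(0.25, 4))

  expect_error(diet_proportions(tibble::tibble(sample_id = "s1", a = 0L)),
               "zero total reads")

  # closure across a multi-sample table
  props <- diet_proportions(toy_counts())
  sums <- tapply(props$proportion, props$sample_id, sum)
  expect_equal(as.numeric(sums), rep(1, 3), tolerance = 1e-9)
})

test_that("order lumping sums member species and conserves closure", {
  ann <- toy_annotation()
  props <- props_from_list(list(
    s1 = c(chinook = 0.2, coho = 0.3, herring = 0.5)
  ))
  ord <- aggregate_orders(props, ann)
  expect_equal(ord$proportion[ord$order == "Salmoniformes"], 0.5)

  # all species in distinct orders: output equals input
  props2 <- props_from_list(list(s1 = c(herring = 0.4, hake = 0.35, sole = 0.25)))
  ord2 <- aggregate_orders(props2, ann)
  expect_equal(sort(ord2$proportion), sort(props2$proportion))

  # six-species mixed example, hand-added totals
  props6 <- props_from_list(list(s1 = c(
    herring = 0.10, hake = 0.15, sole = 0.20, squid = 0.05,
    chinook = 0.30, coho = 0.20
  )))
  ord6 <- aggregate_orders(props6, ann)
  expect_equal(sum(ord6$proportion), 1, tolerance = 1e-9)
  expect_equal(ord6$proportion[ord6$order == "Salmoniformes"], 0.5)

  # permutation invariance in taxon order
  shuffled <- props6[c(4, 2, 6, 1, 5, 3), ]
  expect_equal(dplyr::arrange(aggregate_orders(shuffled, ann), order),
               dplyr::arrange(ord6, order))

  expect_error(aggregate_orders(props_from_list(list(s1 = c(mystery = 1))), ann),
               "mystery")
})

test_that("juvenile-ratio lookup walks sample, month, season, default", {
  hp <- tibble::tibble(
    scope = c("sample", "month", "season", "season"),
    sample_id = c("s9", NA, NA, NA),
    location = c(NA, "CB", "CB", NA),
    year = c(NA, 2013L, 2013L, NA),
    month = c(NA, 6L, NA, NA),
    season = c(NA, NA, "summer", "summer"),
    species = "chinook",
    juvenile_fraction = c(0.9, 0.7, 0.5, 0.3)
  )
  r <- lookup_juvenile_ratio(hp, "chinook", sample_id = "s9",
                             location = "CB", year = 2013, month = 6)
  expect_equal(r, list(juvenile_fraction = 0.9, scope = "sample"))

  r <- lookup_juvenile_ratio(hp, "chinook", sample_id = "other",
                             location = "CB", year = 2013, month = 6)
  expect_equal(r, list(juvenile_fraction = 0.7, scope = "month"))

  r <- lookup_juvenile_ratio(hp, "chinook", sample_id = "other",
                             location = "CB", year = 2013, month = 7)
  expect_equal(r, list(juvenile_fraction = 0.5, scope = "season"))

  r <- lookup_juvenile_ratio(hp, "chinook", sample_id = "other",
                             location = "FR", year = 2012, month = 7)
  expect_equal(r, list(juvenile_fraction = 0.3, scope = "season"))

  empty <- hp[0, ]
  r <- lookup_juvenile_ratio(empty, "chinook", sample_id = "s9",
                             location = "CB", year = 2013, month = 6)
  expect_equal(r, list(juvenile_fraction = 0, scope = "default-adult"))
})

test_that("salmonid split conserves the order total and honours ratios", {
  ann <- toy_annotation()
  props <- props_from_list(list(s1 = c(chinook = 0.40, herring = 0.60)))
  ords <- aggregate_orders(props, ann)
  meta <- tibble::tibble(sample_id = "s1", location = "CB", year = 2013L, month = 6L)
  hp <- tibble::tibble(scope = "month", sample_id = NA_character_, location = "CB",
                       year = 2013L, month = 6L, season = NA_character_,
                       species = "chinook", juvenile_fraction = 0.25)
  out <- split_salmonids(ords, props, ann, metadata = meta, hardpart = hp)
  expect_equal(out$proportion[out$order == "Juvenile Salmoniformes"], 0.10)
  expect_equal(out$proportion[out$order == "Adult Salmoniformes"], 0.30)
  expect_equal(
    out$proportion[out$order == "Juvenile Salmoniformes"] +
      out$proportion[out$order == "Adult Salmoniformes"],
    out$proportion[out$order == "Salmoniformes"],
    tolerance = 1e-12
  )
  # base orders still close to 1 without the pseudo-orders
  base <- out[!out$order %in% c("Juvenile Salmoniformes", "Adult Salmoniformes"), ]
  expect_equal(sum(base$proportion), 1, tolerance = 1e-9)

  # no hard-part data: everything adult
  out0 <- split_salmonids(ords, props, ann, metadata = meta, hardpart = NULL)
  expect_equal(out0$proportion[out0$order == "Juvenile Salmoniformes"], 0)
  expect_equal(out0$proportion[out0$order == "Adult Salmoniformes"], 0.40)

  # two salmonid species with different ratios
  props2 <- props_from_list(list(s1 = c(chinook = 0.2, coho = 0.1, herring = 0.7)))
  ords2 <- aggregate_orders(props2, ann)
  hp2 <- tibble::tibble(scope = "month", sample_id = NA_character_, location = "CB",
                        year = 2013L, month = 6L, season = NA_character_,
                        species = c("chinook", "coho"),
                        juvenile_fraction = c(0.5, 1.0))
  out2 <- split_salmonids(ords2, props2, ann, metadata = meta, hardpart = hp2)
  expect_equal(out2$proportion[out2$order == "Juvenile Salmoniformes"], 0.20)
  expect_equal(out2$proportion[out2$order == "Adult Salmoniformes"], 0.10)
})

test_that("benthic fraction sums benthic-annotated proportions", {
  ann <- toy_annotation()
  expect_equal(
    benthic_fraction(props_from_list(list(s1 = c(sole = 1))), ann)$benthic_fraction, 1
  )
  expect_equal(
    benthic_fraction(props_from_list(list(s1 = c(herring = 1))), ann)$benthic_fraction, 0
  )
  # sole 0.15 + (second benthic taxon) 0.25
  ann2 <- dplyr::bind_rows(ann, tibble::tibble(
    taxon = "flounder", order = "Pleuronectiformes", habitat = "benthic",
    is_salmonid = FALSE, species = "flounder"
  ))
  bf <- benthic_fraction(
    props_from_list(list(s1 = c(sole = 0.15, flounder = 0.25, herring = 0.6))), ann2
  )
  expect_equal(bf$benthic_fraction, 0.40)

  # unannotated taxa warn and count as non-benthic; complement identity holds
  expect_warning(
    bf2 <- benthic_fraction(props_from_list(list(s1 = c(mystery = 0.5, sole = 0.5))), ann),
    "unknown habitat"
  )
  expect_equal(bf2$benthic_fraction, 0.5)
  fully <- props_from_list(list(s1 = c(sole = 0.3, herring = 0.3, hake = 0.4)))
  bf3 <- benthic_fraction(fully, ann)
  non_benthic <- 1 - bf3$benthic_fraction
  expect_equal(bf3$benthic_fraction + non_benthic, 1)
  expect_equal(non_benthic, 0.7)
})
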