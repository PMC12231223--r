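# Printed reference values for the 22-category C. nigriocularis composition
# table (category, %F, %N, %V, IRI at two decimals).
published_table <- tibble::tribble(
  ~category, ~pct_F, ~pct_N, ~pct_V, ~iri,
  "Lumbricidae", 1.33, 0.74, 15.73, 5.93,
  "Achatinidae", 6.67, 5.65, 19.69, 10.67,
  "Stylommatophora other", 1.33, 0.25, 0.02, 0.53,
  "Araneae", 26.67, 35.87, 10.44, 24.33,
  "Opiliones", 17.33, 23.59, 8.86, 16.59,
  "Uropigi", 1.33, 4.67, 10.91, 5.64,
  "Scolopendridae", 8.00, 3.44, 11.32, 7.59,
  "Armadillidiidae", 1.33, 0.49, 0.42, 0.75,
  "Blattidae", 6.67, 11.06, 8.59, 8.77,
  "Byrrhidae", 1.33, 0.25, 0.10, 0.56,
  "Elateroidea", 1.33, 0.25, 3.18, 1.59,
  "Culicidae", 1.33, 0.25, 0.15, 0.58,
  "Cicadellidae", 1.33, 0.25, 0.11, 0.56,
  "Pentatomidae", 2.67, 0.49, 1.68, 1.61,
  "Apidae", 1.33, 0.49, 2.09, 1.31,
  "Formicidae", 5.33, 2.21, 0.30, 2.62,
  "Termitidae", 4.00, 2.46, 0.67, 2.38,
  "Hepialidae", 1.33, 0.25, 1.41, 1.00,
  "Lepidoptera other", 1.33, 0.25, 0.74, 0.77,
  "Mantidae", 1.33, 1.47, 0.90, 1.23,
  "Acrididae", 5.33, 4.67, 2.61, 4.20,
  "Tetrigidae", 1.33, 0.98, 0.06, 0.79)

test_that("prolate-spheroid volume matches closed-form and sphere limits", {
  expect_equal(prey_volume(10, 2), 20.944, tolerance = 1e-4)
  expect_equal(prey_volume(10, 2), (4 * pi / 3) * 5 * 1^2)
  expect_equal(prey_volume(2, 2), 4.18879, tolerance = 1e-5)  # sphere, d = 2
  expect_equal(prey_volume(2, 2), (4 / 3) * pi * 1^3)
  expect_equal(prey_volume(10, 2, pi_mode = "3.14"), 20.933, tolerance = 1e-3)
  expect_error(prey_volume(-1, 2), class = "gekkodiet_domain_error")
  expect_error(prey_volume(1, 0), class = "gekkodiet_domain_error")
})

test_that("volume is strictly increasing in each dimension", {
  withr::with_seed(5, {
    l <- runif(50, 0.5, 60); w <- runif(50, 0.2, 8)
    expect_true(all(prey_volume(l + 0.1, w) > prey_volume(l, w)))
    expect_true(all(prey_volume(l, w + 0.1) > prey_volume(l, w)))
  })
})

test_that("the published composition table is reproduced at two decimals", {
  comp <- composition_from_counts(nigriocularis_composition())
  out <- format(comp)
  got <- out[match(published_table$category, out$category), ]
  # %F, %N and IRI agree exactly at the printed precision; %V agrees within
  # one unit in the last printed place (the printed V column is itself
  # rounded, so one cell sits on a half boundary)
  expect_equal(got$pct_F, published_table$pct_F, tolerance = 1e-9)
  expect_equal(got$pct_N, published_table$pct_N, tolerance = 1e-9)
  expect_true(all(abs(got$pct_V - published_table$pct_V) <= 0.01 + 1e-9))
  expect_equal(got$iri, published_table$iri, tolerance = 1e-9)
  expect_equal(sum(out$iri), 100.00, tolerance = 0.005)
})

test_that("frequency denominator conventions differ as documented", {
  counts <- nigriocularis_composition()
  by_sum <- composition_from_counts(counts, freq_denominator = "sum_of_F")
  by_stomach <- composition_from_counts(counts, freq_denominator = "n_stomachs",
                                        n_stomachs = 51)
  ara_sum <- by_sum$pct_F[by_sum$category == "Araneae"]
  ara_sto <- by_stomach$pct_F[by_stomach$category == "Araneae"]
  expect_equal(ara_sum, 100 * 20 / 75)
  expect_equal(ara_sto, 100 * 20 / 51)
  expect_error(composition_from_counts(counts, freq_denominator = "n_stomachs"),
               class = "gekkodiet_domain_error")
})

test_that("a single-category dataset normalises to 100 everywhere", {
  ds <- assemble_dataset(make_specimens(2),
                         make_items(c("S01", "S02"), "Araneae", c(5, 8), c(1, 2)))
  comp <- composition_table(ds)
  expect_equal(comp$pct_F, 100)
  expect_equal(comp$pct_N, 100)
  expect_equal(comp$pct_V, 100)
  expect_equal(comp$iri, 100)
})

test_that("composition_table agrees with a brute-force tally on random data", {
  for (seed in 1:20) {
    ds <- random_small_dataset(seed)
    comp <- composition_table(ds)
    oracle <- oracle_composition(ds$specimens, ds$prey_items)
    got <- as.data.frame(comp)[match(oracle$category, comp$category), ]
    for (col in c("F", "N", "V", "pct_F", "pct_N", "pct_V", "iri")) {
      expect_equal(got[[col]], oracle[[col]], tolerance = 1e-9,
                   info = sprintf("seed %d column %s", seed, col))
    }
    # conservation and normalisation invariants
    expect_equal(sum(comp$N), nrow(ds$prey_items))
    expect_equal(sum(comp$V),
                 sum(prey_volume(ds$prey_items$length_mm, ds$prey_items$width_mm)),
                 tolerance = 1e-6)
    for (col in c("pct_F", "pct_N", "pct_V", "iri")) {
      expect_equal(sum(comp[[col]]), 100, tolerance = 0.05)
    }
  }
})

test_that("percentages and IRI are invariant to the pi convention", {
  ds <- random_small_dataset(42)
  exact <- composition_table(ds, pi_mode = "exact")
  approx <- composition_table(ds, pi_mode = "3.14")
  expect_equal(exact$pct_V, approx$pct_V, tolerance = 1e-12)
  expect_equal(exact$iri, approx$iri, tolerance = 1e-12)
  expect_true(all(approx$V < exact$V))  # 3.14 < pi scales V down only
})

test_that("adding an item of a category never decreases its pctN or IRI", {
  ds <- random_small_dataset(7)
  comp0 <- composition_table(ds)
  target <- comp0$category[which.min(comp0$iri)]
  extra <- make_items(ds$specimens$specimen_id[1], target, 4, 1)
  ds2 <- assemble_dataset(ds$specimens, dplyr::bind_rows(ds$prey_items, extra))
  comp1 <- composition_table(ds2)
  expect_gte(comp1$pct_N[comp1$category == target],
             comp0$pct_N[comp0$category == target])
  expect_gte(comp1$iri[comp1$category == target],
             comp0$iri[comp0$category == target])
})

test_that("IRI ranking reproduces the published order, with and without the
           recurrent-category filter", {
  comp <- composition_from_counts(nigriocularis_composition())
  # strict IRI order over all 22 categories
  expect_equal(rank_by_iri(comp, top_k = 5),
               c("Araneae", "Opiliones", "Achatinidae", "Blattidae",
                 "Scolopendridae"))
  # the headline six are the top six among categories found in >= 2 stomachs:
  # the strict order interleaves two single-stomach categories instead
  expect_equal(rank_by_iri(comp, top_k = 6, min_F = 2),
               c("Araneae", "Opiliones", "Achatinidae", "Blattidae",
                 "Scolopendridae", "Acrididae"))
  expect_equal(rank_by_iri(comp, top_k = 8),
               c("Araneae", "Opiliones", "Achatinidae", "Blattidae",
                 "Scolopendridae", "Lumbricidae", "Uropigi", "Acrididae"))
})

test_that("ranking ties break by item count then lexicographically", {
  counts <- tibble::tibble(
    category = c("Beta", "Alpha", "Gamma"),
    F = c(1, 1, 2), N = c(5, 5, 10), V = c(10, 10, 20))
  comp <- composition_from_counts(counts)
  # Gamma dominates; Alpha and Beta tie on iri and N -> alphabetical
  expect_equal(rank_by_iri(comp), c("Gamma", "Alpha", "Beta"))
  # constructed iri tie with different N: each row's percentages sum to 150
  counts2 <- tibble::tibble(
    category = c("Low", "High"), F = c(1, 1), N = c(1, 4), V = c(8, 2))
  comp2 <- composition_from_counts(counts2)
  expect_equal(diff(range(comp2$iri)), 0, tolerance = 1e-12)
  expect_equal(rank_by_iri(comp2), c("High", "Low"))
})

test_that("size summaries use the sample SD and handle degenerate n", {
  ds <- assemble_dataset(make_specimens(1),
                         make_items(c("S01", "S01"), "Araneae", c(2, 4), c(1, 1)))
  s <- size_summary(ds, "length")
  expect_equal(s$n, 2)
  expect_equal(s$mean, 3)
  expect_equal(s$sd, sqrt(2), tolerance = 1e-9)
  expect_equal(c(s$min, s$max), c(2, 4))

  one <- assemble_dataset(make_specimens(1),
                          make_items("S01", "Araneae", 5, 1))
  s1 <- size_summary(one, "length")
  expect_equal(s1$n, 1)
  expect_equal(s1$sd, 0)

  expect_error(size_summary(ds, "length", groups = "male"),
               class = "gekkodiet_domain_error")
})

test_that("count_per_stomach aggregates per specimen and can include empties", {
  specimens <- make_specimens(3)
  items <- make_items(c("S01", "S01", "S02"), "Araneae", c(2, 3, 4), c(1, 1, 1))
  ds <- assemble_dataset(specimens, items)
  s <- size_summary(ds, "count_per_stomach")
  expect_equal(s$n, 2)           # S03 has no items and is excluded by default
  expect_equal(s$mean, 1.5)
  s_all <- size_summary(ds, "count_per_stomach", include_empty = TRUE)
  expect_equal(s_all$n, 3)
  expect_equal(s_all$min, 0)
})

test_that("trophic spectrum counts distinct categories per group", {
  specimens <- dplyr::bind_rows(make_specimens(2, "male"),
                                tibble::tibble(specimen_id = "F01", group = "female",
                                               svl_mm = 100, mw_mm = 20, bm_g = 20))
  items <- make_items(c("S01", "S02", "F01", "F01"),
                      c("Araneae", "Blattidae", "Araneae", "Opiliones"),
                      c(5, 6, 7, 8), c(1, 1, 1, 1))
  ds <- assemble_dataset(specimens, items)
  spec <- trophic_spectrum(ds)
  expect_equal(spec$n_categories[spec$group == "male"], 2L)
  expect_equal(spec$n_categories[spec$group == "female"], 2L)
  expect_equal(trophic_spectrum(ds, by = "none")$n_categories, 3L)

  one_cat <- assemble_dataset(specimens,
                              make_items(c("S01", "F01"), "Araneae",
                                         c(5, 6), c(1, 1)))
  spec1 <- trophic_spectrum(one_cat)
  expect_equal(spec1$n_categories, c(1L, 1L))
})

test_that("composition of an empty selection errors rather than returning", {
  ds <- random_small_dataset(1)
  expect_error(composition_table(ds, groups = "male"),
               class = "gekkodiet_domain_error")
})
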