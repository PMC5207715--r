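test_that("proportion test matches the 2x2 oracle and is symmetric", {
  t0 <- proportion_test(10, 100, 10, 100)
  expect_equal(t0$chi2, 0, tolerance = 1e-12)
  expect_equal(t0$direction, "under")  # tie breaks as under

  t1 <- proportion_test(50, 100, 10, 100)
  expect_equal(t1$chi2, h_chi2_2x2(50, 100, 10, 100), tolerance = 1e-9)
  expect_equal(t1$direction, "over")

  t2 <- proportion_test(10, 100, 50, 100)
  expect_identical(t1$chi2, t2$chi2)

  # extreme under-representation, exact-test cross check
  t3 <- proportion_test(0, 100, 3, 3)
  expect_lt(t3$p, 0.001)
  expect_equal(t3$direction, "under")
  fx <- stats::fisher.test(matrix(c(0, 100, 3, 0), 2))
  expect_lt(fx$p.value, 0.001)

  expect_error(proportion_test(1, 0, 1, 2))
})

test_that("representation table computes fractions and within-realm tests", {
  g <- h_groups(rate = 1, n_species = c(10, 5),
                taxonomic_group = c("Birds", "Mammals"))
  d <- h_sim(g)$dataset
  # reference mirroring the dataset's proportions exactly: nothing significant
  ref <- data.frame(system = "terrestrial", realm = "Palearctic",
                    taxonomic_group = c("Birds", "Mammals"),
                    known_species = c(100, 50))
  tab <- representation_table(d, ref)
  expect_false(any(tab$significant))
  expect_equal(tab$fraction, c(10 / 100, 5 / 50))

  # group present in reference but absent from data: fraction 0, under
  ref2 <- rbind(ref, data.frame(system = "terrestrial",
                                realm = "Palearctic",
                                taxonomic_group = "Herps",
                                known_species = 3))
  tab2 <- representation_table(d, ref2)
  herps <- tab2[tab2$taxonomic_group == "Herps", ]
  expect_equal(herps$fraction, 0)
  expect_equal(herps$direction, "under")

  # dataset group missing from the reference is an error
  expect_error(representation_table(d, ref[1, ]), "Mammals")
})

test_that("published representation fractions reproduce from their counts", {
  # Nearctic birds: 492 species of a possible 725 -> 68%;
  # Afrotropical herps: 18 of 2480 -> 0.7%, below the 1% exclusion line
  g <- h_groups(rate = 1, n_species = c(492, 18),
                realm = c("Nearctic", "Afrotropical"),
                taxonomic_group = c("Birds", "Herps"))
  d <- h_sim(g)$dataset
  ref <- data.frame(system = "terrestrial",
                    realm = c("Nearctic", "Afrotropical"),
                    taxonomic_group = c("Birds", "Herps"),
                    known_species = c(725, 2480))
  tab <- representation_table(d, ref)
  expect_equal(round(100 * tab$fraction[tab$realm == "Nearctic"]), 68)
  expect_lt(tab$fraction[tab$realm == "Afrotropical"], 0.01)
})

test_that("Red List comparison labels directions and handles Criterion A", {
  # identical category distributions: nothing significant
  mk_cats <- function(taxon, counts) {
    data.frame(species_binomial = sprintf("%s sp%d", taxon,
                                          seq_len(sum(counts))),
               taxon = taxon,
               category = rep(names(counts), counts),
               stringsAsFactors = FALSE)
  }
  counts <- c(LC = 60, `NT/LR` = 15, VU = 12, EN = 8, CR = 5)
  cats <- mk_cats("Mammalia", counts)
  ref <- data.frame(taxon = "Mammalia", category = names(counts),
                    known_species = unname(counts) * 10)
  tab <- redlist_comparison(cats, ref)
  expect_false(any(tab$significant))

  # NT and LR merge into one category
  cats2 <- cats; cats2$category[cats2$category == "NT/LR"] <- "NT"
  tab2 <- redlist_comparison(cats2, ref)
  expect_equal(tab2$n_in_dataset, tab$n_in_dataset)

  expect_error(redlist_comparison(
    data.frame(species_binomial = "X y", taxon = "Aves", category = "DD"),
    ref), "unknown Red List category")

  # no Criterion A flags: threatened rows empty with a warning
  ref$known_criterion_a <- c(NA, NA, 50, 30, 20)
  expect_warning(tab3 <- redlist_comparison(cats, ref,
                                            criterion_a_only = TRUE),
                 "Criterion A")
  expect_true(all(tab3$n_in_dataset[tab3$category %in%
                                      c("VU", "EN", "CR")] == 0))
  # flagged threatened species survive the subset on both sides
  cats$criterion_a <- cats$category %in% c("VU", "EN", "CR")
  tab4 <- redlist_comparison(cats, ref, criterion_a_only = TRUE)
  expect_equal(tab4$known_species[tab4$category == "VU"], 50)
  expect_equal(tab4$n_in_dataset[tab4$category == "VU"], 12)
})
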