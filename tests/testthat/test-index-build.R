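test_that("group means average species with data per year", {
  s1 <- c(`1971` = 0.2); s2 <- c(`1971` = -0.2)
  g <- group_mean(list(s1, s2))
  expect_equal(unname(g$lambda), 0)
  expect_equal(unname(g$n_species), 2)
  expect_equal(group_mean(list(s1))$lambda, s1)
  # staggered coverage, brute-force cross-check
  a <- stats::setNames(c(0.1, 0.2, 0.3), 1971:1973)
  b <- stats::setNames(c(-0.1, 0.5), 1973:1974)
  g2 <- group_mean(list(a, b))
  expect_equal(unname(g2$lambda),
               c(0.1, 0.2, mean(c(0.3, -0.1)), 0.5))
})

test_that("weighted combination renormalizes over children present", {
  l1 <- c(`1971` = -0.1); l2 <- c(`1971` = 0.1)
  expect_equal(unname(weighted_combine(list(l1, l2), c(0.433, 0.567))),
               0.433 * -0.1 + 0.567 * 0.1, tolerance = 1e-12)
  expect_equal(unname(weighted_combine(list(l2, l1), c(0.5, 0.5))), 0)
  # child B absent in a year: weights renormalize to child A alone
  a <- c(`1979` = 0.2, `1980` = 0.2)
  b <- c(`1979` = -0.2)
  out <- weighted_combine(list(a, b), c(0.3, 0.7))
  expect_equal(unname(out["1980"]), 0.2)
  expect_error(weighted_combine(list(a, b), c(0, 0)), "all-zero weights")
})

test_that("index reconstruction starts at 1 and multiplies by 10^rate", {
  l <- c(`1971` = 0.1, `1972` = -0.1)
  idx <- lambdas_to_index(l, 1970)
  expect_equal(unname(idx), c(1, 10^0.1, 1))
  expect_equal(names(idx), c("1970", "1971", "1972"))
  expect_equal(unname(lambdas_to_index(c(`1971` = 0, `1972` = 0), 1970)),
               rep(1, 3))
  lc <- stats::setNames(rep(log10(0.98), 42), 1971:2012)
  expect_equal(unname(lambdas_to_index(lc, 1970)[43]), 0.98^42,
               tolerance = 1e-12)
  expect_error(lambdas_to_index(c(`1972` = 0.1), 1970), "consecutive")
})

test_that("annualized rates convert total change to percent per year", {
  expect_equal(annualized_rate(0.42, 42), 100 * (1 - 0.42^(1 / 42)))
  expect_equal(annualized_rate(1, 99), 0)
  expect_lt(annualized_rate(1.384, 42), 0)  # increases come out negative
})

test_that("unweighted hierarchy matches closed forms", {
  # all six zone-by-system subsets share a constant rate
  g <- h_groups(rate = 0.98, n_species = 2,
                system = rep(c("terrestrial", "freshwater", "marine"), 2),
                realm = "R",
                zone = rep(c("tropical", "temperate"), each = 3))
  fit <- assemble_lpi_u(h_sim(g)$dataset, cap = Inf,
                        gam_min_points = 999)
  expect_equal(unname(fit$index["2012"]), 0.98^42, tolerance = 1e-10)
  expect_identical(unname(fit$index["1970"]), 1)

  # tropical-only data: renormalization makes the index the tropical index
  g2 <- h_groups(rate = 0.95, zone = "tropical")
  fit2 <- assemble_lpi_u(h_sim(g2)$dataset, cap = Inf, gam_min_points = 999)
  expect_equal(unname(fit2$index["2012"]), 0.95^42, tolerance = 1e-10)

  # two zones with distinct constant rates: 10^(T (a+b)/2)
  g3 <- h_groups(rate = c(0.97, 1.02), zone = c("tropical", "temperate"))
  fit3 <- assemble_lpi_u(h_sim(g3)$dataset, cap = Inf, gam_min_points = 999)
  ab <- (log10(0.97) + log10(1.02)) / 2
  expect_equal(unname(fit3$index["2012"]), 10^(42 * ab), tolerance = 1e-10)
})

test_that("weighted hierarchy applies taxon and realm proportions", {
  g <- h_groups(rate = c(10^-0.01, 10^0.01),
                taxonomic_group = c("Birds", "Mammals"))
  sim <- h_sim(g)
  w <- sim_weights(sim$config, taxon_weight = c(0.9, 0.1))
  fit <- assemble_lpi_d(sim$dataset, w, cap = Inf, gam_min_points = 999)
  expect_equal(unname(fit$index["2012"]), 10^(42 * -0.008),
               tolerance = 1e-10)
  expect_identical(unname(fit$index["1970"]), 1)

  # a group without a weight is an error naming the key
  w2 <- weight_scheme(
    taxon = data.frame(system = "terrestrial", realm = "Palearctic",
                       taxon = "Birds", weight = 1),
    realm = data.frame(system = "terrestrial", realm = "Palearctic",
                       weight = 1))
  expect_error(assemble_lpi_d(sim$dataset, w2, cap = Inf,
                              gam_min_points = 999),
               "Mammals")
})

test_that("record order never changes the index", {
  g <- h_groups(rate = c(0.98, 1.01, 0.9), n_species = c(3, 2, 4),
                n_pops = 2,
                taxonomic_group = c("Birds", "Mammals", "Herps"))
  sim <- h_sim(g, noise = 0.1, seed = 11, p_missing = 0.2,
               series_length = c(4, 30))
  d <- sim$dataset
  perm <- sample(seq_len(nrow(d$records)))
  d2 <- structure(list(records = d$records[perm, ], series = d$series[perm],
                       window = d$window), class = "lpd_dataset")
  f1 <- suppressWarnings(lpi(d, method = "unweighted"))
  f2 <- suppressWarnings(lpi(d2, method = "unweighted"))
  expect_identical(f1$index, f2$index)
})

test_that("raising one group's trend never lowers the index", {
  base_rates <- c(0.95, 1.0)
  g1 <- h_groups(rate = base_rates, taxonomic_group = c("Birds", "Mammals"))
  g2 <- h_groups(rate = c(0.99, 1.0), taxonomic_group = c("Birds", "Mammals"))
  f1 <- assemble_lpi_u(h_sim(g1)$dataset, cap = Inf, gam_min_points = 999)
  f2 <- assemble_lpi_u(h_sim(g2)$dataset, cap = Inf, gam_min_points = 999)
  expect_true(all(f2$index >= f1$index - 1e-12))
})

test_that("low-representation groups are excluded by threshold", {
  g <- h_groups(rate = c(0.98, 1.0), n_species = c(2, 3),
                taxonomic_group = c("Herps", "Birds"))
  d <- h_sim(g)$dataset
  rep_tab <- data.frame(system = "terrestrial", realm = "Palearctic",
                        taxonomic_group = c("Herps", "Birds"),
                        fraction = c(0.007, 0.5))
  out <- exclude_low_representation(d, rep_tab)
  expect_false("Herps" %in% out$records$taxonomic_group)
  expect_equal(attr(out, "removed_groups")$taxonomic_group, "Herps")
  # threshold zero keeps everything
  out0 <- exclude_low_representation(d, rep_tab, threshold = 0)
  expect_equal(nrow(out0$records), nrow(d$records))
  # everything below threshold: empty dataset with warning
  expect_warning(out1 <- exclude_low_representation(d, rep_tab,
                                                    threshold = 0.9),
                 "empty")
  expect_equal(nrow(out1$records), 0L)
})
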