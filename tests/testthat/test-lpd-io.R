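test_that("wide CSV parsing handles NULL/empty/NA cells, zeros, and short rows", {
  p <- h_csv(c(
    "ID,Binomial,Class,System,Realm,Zone,Units,Source,Confidential,1970,1971,1972,1973",
    "p1,Aquila chrysaetos,Aves,terrestrial,Palearctic,temperate,pairs,s1,FALSE,100,NULL,,400",
    "p2,Salmo trutta,Actinopterygii,freshwater,Palearctic,temperate,counts,s2,FALSE,0,NA,5,NULL",
    "p3,Bufo bufo,Amphibia,terrestrial,Palearctic,temperate,counts,s3,TRUE,NULL,NULL,NULL,NULL",
    "p4,Rana sp,Amphibia,terrestrial,Palearctic,temperate,counts,s4,FALSE,7,NULL,NULL,NULL"))
  expect_warning(d <- read_population_table(p), "p3.*p4|p4.*p3")
  expect_equal(nrow(d$records), 2L)
  expect_equal(d$series$p1, c(`1970` = 100, `1973` = 400))
  # zero is a retained observation; class map pools amphibians into Herps
  expect_equal(unname(d$series$p2["1970"]), 0)
  expect_equal(d$records$taxonomic_group,
               c("Birds", "Fish"))
  expect_true(d$records$confidential[1] == FALSE)
})

test_that("malformed headers are rejected by name", {
  p <- h_csv(c("ID,Binomial,Class,System,Realm,Zone,1970,banana",
               "p1,A b,Aves,terrestrial,Palearctic,temperate,1,2"))
  expect_error(read_population_table(p), "banana")
  p2 <- h_csv(c("ID,Class,System,Realm,Zone,1970",
                "p1,Aves,terrestrial,Palearctic,temperate,1"))
  expect_error(read_population_table(p2), "Binomial")
})

test_that("write/read round trip preserves observed values and gaps", {
  sim <- h_sim(h_groups(c(0.98, 1.03), n_species = 3, n_pops = 2,
                        taxonomic_group = c("Birds", "Mammals")),
               noise = 0.1, seed = 42, p_missing = 0.3,
               series_length = c(5, 30))
  f <- tempfile(fileext = ".csv")
  write_population_table(sim$dataset, f)
  back <- read_population_table(f)
  expect_equal(back$records$population_id, sim$dataset$records$population_id)
  for (id in back$records$population_id)
    expect_equal(back$series[[id]], sim$dataset$series[[id]])
})

test_that("window truncation re-applies the two-observation rule", {
  rec <- data.frame(population_id = c("a", "b"),
                    species_binomial = "X y", taxonomic_group = "Birds",
                    system = "terrestrial", realm = "Palearctic",
                    zone = "temperate")
  ser <- list(a = c(`1965` = 5, `1966` = 6, `1971` = 7),
              b = c(`1971` = 1, `1980` = 2))
  expect_warning(d <- lpd_dataset(rec, ser, window = c(1970, 2012)),
                 "fewer than 2")
  expect_equal(d$records$population_id, "b")
  # pre-window observations are gone from retained series too
  d2 <- lpd_dataset(rec, ser, window = c(1960, 2012))
  expect_equal(length(d2$series$a), 3L)
})

test_that("realm and class merges are applied at read time", {
  p <- h_csv(c("ID,Binomial,Class,System,Realm,Zone,1970,1971",
               "p1,A b,Reptilia,terrestrial,Australasia,tropical,1,2",
               "p2,C d,Amphibia,terrestrial,Indo-Malaya,tropical,3,4"))
  d <- read_population_table(p)
  expect_equal(unique(d$records$realm), "Indo-Pacific")
  expect_equal(unique(d$records$taxonomic_group), "Herps")
})

test_that("weight schemes renormalize per parent and reject bad input", {
  w <- read_weight_scheme(
    system.file("extdata", "weights_synthetic.csv", package = "lpindex"))
  # published Palearctic values survive the round trip
  i <- w$taxon$system == "terrestrial" & w$taxon$realm == "Palearctic" &
    w$taxon$taxon == "Birds"
  expect_equal(w$taxon$weight[i], 0.433, tolerance = 1e-9)
  j <- w$realm$system == "terrestrial" & w$realm$realm == "Palearctic"
  expect_equal(w$realm$weight[j], 0.106, tolerance = 1e-3)
  # per-parent sums are 1 within 1e-9
  for (key in split(w$taxon$weight, paste(w$taxon$system, w$taxon$realm)))
    expect_equal(sum(key), 1, tolerance = 1e-9)
  for (key in split(w$realm$weight, w$realm$system))
    expect_equal(sum(key), 1, tolerance = 1e-9)
  expect_equal(sum(w$system), 1, tolerance = 1e-9)

  # raw counts normalize: (2, 2) -> (0.5, 0.5)
  ws <- weight_scheme(
    taxon = data.frame(system = "terrestrial", realm = "R",
                       taxon = c("Birds", "Mammals"), weight = c(2, 2)),
    realm = data.frame(system = "terrestrial", realm = "R", weight = 1))
  expect_equal(ws$taxon$weight, c(0.5, 0.5))

  expect_error(weight_scheme(
    taxon = data.frame(system = "terrestrial", realm = "R",
                       taxon = "Birds", weight = -1),
    realm = data.frame(system = "terrestrial", realm = "R", weight = 1)),
    "negative")
  expect_error(weight_scheme(
    taxon = data.frame(system = "terrestrial", realm = "R",
                       taxon = c("Birds", "Birds"), weight = c(1, 1)),
    realm = data.frame(system = "terrestrial", realm = "R", weight = 1)),
    "duplicate")
})

test_that("YAML weight schemes read like CSV ones", {
  y <- tempfile(fileext = ".yml")
  writeLines(c(
    "- {level: taxon, system: terrestrial, realm: R, taxon: Birds, weight: 3}",
    "- {level: taxon, system: terrestrial, realm: R, taxon: Mammals, weight: 1}",
    "- {level: realm, system: terrestrial, realm: R, weight: 1}"), y)
  w <- read_weight_scheme(y)
  expect_equal(w$taxon$weight, c(0.75, 0.25))
})
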