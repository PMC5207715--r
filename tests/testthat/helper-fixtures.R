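# group table shorthand for sim_config(); arguments recycle
h_groups <- function(rate, n_species = 3, n_pops = 1,
                     system = "terrestrial", realm = "Palearctic",
                     taxonomic_group = "Birds", zone = "temperate") {
  data.frame(system = system, realm = realm,
             taxonomic_group = taxonomic_group, zone = zone,
             rate = rate, n_species = n_species, n_pops = n_pops,
             stringsAsFactors = FALSE)
}

# deterministic (noise-free by default) simulated dataset
h_sim <- function(groups, noise = 0, seed = 1, ...) {
  simulate_lpd(sim_config(groups, obs_noise_sd = noise, seed = seed, ...))
}

# tiny wide-format CSV on disk
h_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# independent 2x2 chi-squared oracle: expected counts from the margins,
# Yates-style correction capped at |O - E|
h_chi2_2x2 <- function(x1, n1, x2, n2, correct = TRUE) {
  O <- c(x1, n1 - x1, x2, n2 - x2)
  N <- n1 + n2
  p <- (x1 + x2) / N
  E <- c(n1 * p, n1 * (1 - p), n2 * p, n2 * (1 - p))
  y <- if (correct) min(0.5, abs(O[1] - E[1])) else 0
  sum((abs(O - E) - y)^2 / E)
}
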