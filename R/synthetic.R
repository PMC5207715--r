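#' Configuration for the synthetic dataset generator
#'
#' Describes a world of species groups with known constant annual growth
#' rates, from which [simulate_lpd()] draws LPD-format datasets and
#' [true_index()] computes the analytic expectation of the index. Each row
#' of `groups` is one system-realm-taxon cell of the hierarchy with its
#' own true multiplicative annual rate.
#'
#' @param groups Data frame with columns `system`, `realm`,
#'   `taxonomic_group`, `zone`, `rate` (true annual multiplicative rate,
#'   > 0, e.g. 0.98 for a 2% yearly decline), `n_species`, `n_pops`
#'   (populations per species).
#' @param window Index window `c(base_year, final_year)`.
#' @param obs_noise_sd Standard deviation of multiplicative lognormal
#'   observation noise on the log10 scale (0 = noiseless).
#' @param p_missing Probability that any single year's observation is
#'   dropped (subject to the two-observation rule).
#' @param series_length `NULL` for series spanning the full window, or
#'   `c(min, max)` for uniformly drawn series lengths at uniformly drawn
#'   start years.
#' @param init_abundance Range for log-uniform initial abundances, so unit
#'   heterogeneity across populations is exercised.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(groups, window = c(1970L, 2012L),
                       obs_noise_sd = 0.05, p_missing = 0,
                       series_length = NULL,
                       init_abundance = c(10, 10000), seed = 1L) {
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  need <- c("system", "realm", "taxonomic_group", "zone", "rate",
            "n_species", "n_pops")
  miss <- setdiff(need, names(groups))
  if (length(miss))
    stop("groups is missing columns: ", paste(miss, collapse = ", "))
  stopifnot(all(groups$rate > 0), all(groups$n_species >= 1),
            all(groups$n_pops >= 1), obs_noise_sd >= 0,
            p_missing >= 0, p_missing < 1)
  window <- as.integer(window)
  stopifnot(window[1] < window[2])
  if (!is.null(series_length)) {
    stopifnot(length(series_length) == 2L, series_length[1] >= 2,
              series_length[2] >= series_length[1],
              series_length[2] <= window[2] - window[1] + 1L)
  }
  structure(list(groups = groups, window = window,
                 obs_noise_sd = obs_noise_sd, p_missing = p_missing,
                 series_length = series_length,
                 init_abundance = init_abundance, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic LPD-format dataset with known ground truth
#'
#' Each population of group g follows exponential growth
#' `N_t = N_0 * r_g^t` observed with multiplicative lognormal noise
#' `10^eps`, `eps ~ Normal(0, obs_noise_sd)` — noise that is unbiased on
#' the log10 scale on which annual rates are computed. Observations are
#' dropped independently with probability `p_missing`, always leaving at
#' least two; initial abundances are log-uniform so populations differ in
#' units and scale, which the index must be invariant to.
#'
#' @param cfg A [sim_config()].
#' @return List of class `lpd_sim` with elements `dataset` (an
#'   [lpd_dataset()]), `config`, and `truth` (the group table with
#'   `log10_rate` added).
#' @export
simulate_lpd <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  g <- cfg$groups
  base <- cfg$window[1]; final <- cfg$window[2]
  span <- final - base + 1L
  recs <- list(); series <- list(); pid <- 0L
  for (i in seq_len(nrow(g))) {
    for (s in seq_len(g$n_species[i])) {
      binom <- sprintf("Genus sp_g%d_s%d", i, s)
      for (p in seq_len(g$n_pops[i])) {
        pid <- pid + 1L
        if (is.null(cfg$series_length)) {
          start <- base; len <- span
        } else {
          len <- sample(cfg$series_length[1]:cfg$series_length[2], 1L)
          start <- base + sample.int(span - len + 1L, 1L) - 1L
        }
        yrs <- seq(start, start + len - 1L)
        n0 <- 10^stats::runif(1, log10(cfg$init_abundance[1]),
                              log10(cfg$init_abundance[2]))
        mu <- n0 * g$rate[i]^(yrs - start)
        eps <- if (cfg$obs_noise_sd > 0)
          stats::rnorm(len, 0, cfg$obs_noise_sd) else numeric(len)
        obs <- mu * 10^eps
        keep <- stats::runif(len) > cfg$p_missing
        if (sum(keep) < 2L)
          keep[sample.int(len, 2L)] <- TRUE
        x <- stats::setNames(obs[keep], yrs[keep])
        recs[[pid]] <- data.frame(
          population_id = sprintf("pop%05d", pid),
          species_binomial = binom,
          taxonomic_group = g$taxonomic_group[i],
          system = g$system[i], realm = g$realm[i], zone = g$zone[i],
          units = "individuals", source_id = "synthetic",
          confidential = FALSE, stringsAsFactors = FALSE)
        series[[pid]] <- x
      }
    }
  }
  records <- do.call(rbind, recs)
  names(series) <- records$population_id
  d <- lpd_dataset(records, series, window = cfg$window)
  if (!nrow(d$records)) stop("configuration produced an empty dataset")
  truth <- g
  truth$log10_rate <- log10(g$rate)
  structure(list(dataset = d, config = cfg, truth = truth),
            class = "lpd_sim")
}

#' @export
print.lpd_sim <- function(x, ...) {
  cat("<lpd_sim> seed", x$config$seed, "\n")
  print(x$dataset)
  invisible(x)
}

#' Analytic expected index for a simulated world
#'
#' Because every population in a group shares a constant annual log10 rate
#' and the observation noise is mean-zero on the log scale, the expected
#' estimated rate for a group equals `log10(r_g)` and the expected index
#' has a closed form: the nested (weighted) arithmetic means of the group
#' rates, exponentiated cumulatively. Serves as the independent oracle for
#' pipeline validation.
#'
#' For the unweighted hierarchy the first averaging level is species
#' within zone-by-system subsets, so group rates enter weighted by their
#' species counts there; higher levels are equally weighted. For the
#' weighted hierarchy the configured taxon/realm weights are applied with
#' equal system weights.
#'
#' @param cfg A [sim_config()].
#' @param weights A [weight_scheme()]; required for `method = "weighted"`.
#' @param method `"unweighted"` or `"weighted"`.
#' @return Named numeric vector of expected index values for every year in
#'   the window (base year = 1).
#' @export
true_index <- function(cfg, weights = NULL,
                       method = c("unweighted", "weighted")) {
  stopifnot(inherits(cfg, "sim_config"))
  method <- match.arg(method)
  g <- cfg$groups
  lr <- log10(g$rate)
  if (method == "unweighted") {
    sub <- paste(g$zone, g$system, sep = "|")
    sub_lam <- vapply(split(seq_len(nrow(g)), sub), function(i)
      stats::weighted.mean(lr[i], g$n_species[i]), numeric(1))
    sub_zone <- vapply(strsplit(names(sub_lam), "|", fixed = TRUE),
                       `[`, character(1), 1L)
    zone_lam <- vapply(split(sub_lam, sub_zone), mean, numeric(1))
    lam <- mean(zone_lam)
  } else {
    stopifnot(inherits(weights, "weight_scheme"))
    rkey <- paste(g$system, g$realm, sep = "|")
    realm_lam <- vapply(split(seq_len(nrow(g)), rkey), function(i) {
      wt <- .taxon_weights(weights, g$system[i], g$realm[i],
                           g$taxonomic_group[i])
      stats::weighted.mean(lr[i], wt)
    }, numeric(1))
    rsys <- vapply(strsplit(names(realm_lam), "|", fixed = TRUE),
                   `[`, character(1), 1L)
    sys_lam <- vapply(split(seq_along(realm_lam), rsys), function(i) {
      rr <- vapply(strsplit(names(realm_lam)[i], "|", fixed = TRUE),
                   `[`, character(1), 2L)
      wt <- .realm_weights(weights, rsys[i], rr)
      stats::weighted.mean(realm_lam[i], wt)
    }, numeric(1))
    sw <- weights$system[names(sys_lam)]
    if (anyNA(sw)) stop("no system weight for: ",
                        paste(names(sys_lam)[is.na(sw)], collapse = ", "))
    lam <- stats::weighted.mean(sys_lam, unname(sw))
  }
  yrs <- seq(cfg$window[1], cfg$window[2])
  stats::setNames(10^(lam * (yrs - yrs[1])), yrs)
}

#' Weight scheme matching a simulation configuration
#'
#' Convenience constructor: builds a [weight_scheme()] over exactly the
#' groups of a [sim_config()], using supplied taxon weights (or known
#' species counts) and realm weights. With `NULL` arguments the groups'
#' `n_species` are used as known-species counts, which makes the weighted
#' and species-count-weighted hierarchies coincide.
#'
#' @param cfg A [sim_config()].
#' @param taxon_weight Optional numeric vector, one weight per `groups`
#'   row (renormalized within realm).
#' @param realm_weight Optional named-by-key data frame with columns
#'   `system`, `realm`, `weight`; defaults to realms weighted by their
#'   total species counts.
#' @return A [weight_scheme()].
#' @export
sim_weights <- function(cfg, taxon_weight = NULL, realm_weight = NULL) {
  g <- cfg$groups
  tw <- data.frame(system = g$system, realm = g$realm,
                   taxon = g$taxonomic_group,
                   weight = if (is.null(taxon_weight)) g$n_species
                            else taxon_weight,
                   stringsAsFactors = FALSE)
  if (is.null(realm_weight)) {
    agg <- stats::aggregate(
      list(weight = if (is.null(taxon_weight)) g$n_species
                    else taxon_weight),
      by = list(system = g$system, realm = g$realm), FUN = sum)
    realm_weight <- agg
  }
  weight_scheme(taxon = tw, realm = realm_weight)
}
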