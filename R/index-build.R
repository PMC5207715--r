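#' Average species trends within a group
#'
#' Per-year arithmetic mean of annual log10 rates over the species that
#' have a rate in that year, recording how many species contribute.
#'
#' @param species List of named numeric vectors (one per species) or a
#'   species-by-years matrix.
#' @return List with `lambda` (named per-year mean) and `n_species`
#'   (named integer vector).
#' @export
group_mean <- function(species) {
  res <- species_mean_lambdas(species)
  list(lambda = res$lambda, n_species = res$n)
}

# weighted per-year mean over rows of a children-by-years matrix.
# Weights are renormalized over the children that have data in each year;
# a year where every present child has zero weight is an error.
.combine_rows <- function(mat, w) {
  stopifnot(nrow(mat) == length(w))
  if (any(w < 0)) stop("negative weight")
  ok <- !is.na(mat)
  m0 <- mat; m0[!ok] <- 0
  den <- colSums(ok * w)
  bad <- den == 0 & colSums(ok) > 0
  if (any(bad))
    stop("all-zero weights among children present in year(s) ",
         paste(colnames(mat)[bad], collapse = ", "))
  out <- colSums(m0 * w) / den
  out[den == 0] <- NA_real_
  out
}

#' Weighted combination of child trends
#'
#' Per-year weighted arithmetic mean of child annual rates, with the
#' weights renormalized over the children that have data in that year.
#' This is the aggregation rule used at every weighted level of the
#' hierarchy (taxa within realm, realms within system), and — with equal
#' weights — at the unweighted levels too.
#'
#' @param children List of named numeric vectors (one per child group) or a
#'   children-by-years matrix.
#' @param weights Non-negative numeric vector, one per child. Need not sum
#'   to one: renormalization over the children present happens per year.
#' @return Named numeric vector of combined per-year rates.
#' @export
weighted_combine <- function(children, weights) {
  if (is.matrix(children)) m <- children
  else {
    yrs <- sort(unique(unlist(lapply(children, names))))
    m <- matrix(NA_real_, length(children), length(yrs),
                dimnames = list(NULL, yrs))
    for (i in seq_along(children)) m[i, names(children[[i]])] <- children[[i]]
  }
  .combine_rows(m, weights)
}

#' Convert annual rates to an index series
#'
#' Reconstructs the multiplicative index from averaged annual log10 rates:
#' the index is 1 in the base year and each later year multiplies by
#' `10^rate`.
#'
#' @param lambdas Named numeric vector of rates for consecutive years
#'   starting at `base_year + 1`; no gaps, no missing values.
#' @param base_year Reference year whose index value is 1.
#' @return Named numeric vector of index values for
#'   `base_year .. max(year)`.
#' @export
lambdas_to_index <- function(lambdas, base_year) {
  yrs <- as.integer(names(lambdas))
  if (!length(yrs)) stop("empty rate series")
  if (anyNA(lambdas)) stop("missing rate value; fill or drop before indexing")
  if (yrs[1] != base_year + 1L || any(diff(yrs) != 1L))
    stop("rates must cover consecutive years starting at base_year + 1")
  stats::setNames(c(1, 10^cumsum(lambdas)), c(base_year, yrs))
}

#' Average annual rate of change implied by a final index value
#'
#' Converts a total multiplicative change over `n_years` into the constant
#' annual percentage change that would produce it:
#' `100 * (1 - final_index^(1/n_years))`. Positive values are average
#' annual declines, negative values average annual increases.
#'
#' @param final_index Index value at the end of the period (base year = 1).
#' @param n_years Number of yearly steps in the period.
#' @return Percent per year.
#' @export
annualized_rate <- function(final_index, n_years) {
  stopifnot(final_index > 0, n_years >= 1)
  100 * (1 - final_index^(1 / n_years))
}

# ---- hierarchy internals ----------------------------------------------

# species-level rate matrices per lowest-level group.
# by: record columns defining the group key. Populations are averaged
# within species inside each group first.
.species_matrices <- function(pl, by) {
  rec <- pl$records
  key <- do.call(paste, c(rec[by], sep = "|"))
  out_mats <- list(); out_keys <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    sp <- rec$species_binomial[rows]
    mats <- t(vapply(split(rows, sp), function(idx)
      species_mean_lambdas(pl$lambda[idx, , drop = FALSE])$lambda,
      numeric(ncol(pl$lambda))))
    colnames(mats) <- colnames(pl$lambda)
    out_mats[[k]] <- mats
    out_keys[[k]] <- rec[rows[1], by, drop = FALSE]
  }
  keys <- do.call(rbind, out_keys)
  rownames(keys) <- NULL
  list(mats = out_mats, keys = keys)
}

# per-group species means, with optional bootstrap row resampling
.group_lambda_matrix <- function(sm, idx = NULL) {
  g <- length(sm$mats)
  out <- matrix(NA_real_, g, ncol(sm$mats[[1]]),
                dimnames = list(names(sm$mats), colnames(sm$mats[[1]])))
  for (i in seq_len(g)) {
    m <- sm$mats[[i]]
    if (!is.null(idx)) m <- m[idx[[i]], , drop = FALSE]
    out[i, ] <- species_mean_lambdas(m)$lambda
  }
  out
}

# unweighted hierarchy: 6 zone-by-system subsets -> zones -> global
# (or systems first when order = "zones_within_system")
.aggregate_u <- function(glam, keys, order = "systems_within_zone") {
  lvl1 <- if (order == "systems_within_zone") keys$zone else keys$system
  mids <- t(vapply(split(seq_len(nrow(glam)), lvl1), function(i)
    .combine_rows(glam[i, , drop = FALSE], rep(1, length(i))),
    numeric(ncol(glam))))
  .combine_rows(mids, rep(1, nrow(mids)))
}

# weighted hierarchy: taxa (taxon weights) -> realms (realm weights)
# -> systems (equal by default)
.aggregate_d <- function(glam, keys, w) {
  realms <- list(); rkeys <- list()
  for (k in unique(paste(keys$system, keys$realm, sep = "|"))) {
    i <- which(paste(keys$system, keys$realm, sep = "|") == k)
    wt <- .taxon_weights(w, keys$system[i], keys$realm[i],
                         keys$taxonomic_group[i])
    realms[[k]] <- .combine_rows(glam[i, , drop = FALSE], wt)
    rkeys[[k]] <- keys[i[1], c("system", "realm")]
  }
  rk <- do.call(rbind, rkeys)
  rmat <- do.call(rbind, realms)
  systems <- list()
  for (s in unique(rk$system)) {
    i <- which(rk$system == s)
    wt <- .realm_weights(w, rk$system[i], rk$realm[i])
    systems[[s]] <- .combine_rows(rmat[i, , drop = FALSE], wt)
  }
  smat <- do.call(rbind, systems)
  sw <- w$system[rownames(smat)]
  if (anyNA(sw))
    stop("no system weight for: ",
         paste(rownames(smat)[is.na(sw)], collapse = ", "))
  .combine_rows(smat, unname(sw))
}

# lambda vector for one assembled index; idx (named list of row indices
# per group) supports bootstrap resampling
.build_lambda <- function(sm, type, w = NULL,
                          order = "systems_within_zone", idx = NULL) {
  glam <- .group_lambda_matrix(sm, idx)
  if (type == "U") .aggregate_u(glam, sm$keys, order)
  else .aggregate_d(glam, sm$keys, w)
}

.finish_index <- function(lambda, pl, method) {
  if (anyNA(lambda)) {
    warning("no data in year(s) ",
            paste(names(lambda)[is.na(lambda)], collapse = ", "),
            "; index held flat there", call. = FALSE)
    lambda[is.na(lambda)] <- 0
  }
  structure(list(
    index = lambdas_to_index(lambda, pl$window[1]),
    lambda = lambda,
    method = method,
    n_species = length(unique(pl$records$species_binomial)),
    n_populations = nrow(pl$records),
    pop_method = table(pl$method),
    n_clipped = pl$n_clipped,
    window = pl$window), class = "lpi_index")
}

.as_pop_lambdas <- function(d, ...) {
  if (inherits(d, "population_lambdas")) d else population_lambdas(d, ...)
}

#' Assemble the unweighted index (LPI-U)
#'
#' Species trends are averaged within each of the six zone-by-system
#' subsets (tropical/temperate crossed with terrestrial, freshwater,
#' marine); the three system trends are averaged equally within each zone;
#' the two zone trends are averaged equally; and the averaged rates are
#' converted to an index with baseline 1 in the base year. Empty subsets
#' are simply absent and the equal weights renormalize over the subsets
#' present each year.
#'
#' @param d An [lpd_dataset()] or a precomputed [population_lambdas()].
#' @param order `"systems_within_zone"` (default: systems averaged within
#'   each zone, then zones) or `"zones_within_system"`. The two differ only
#'   when subsets are missing years.
#' @param ... Passed to [population_lambdas()] when `d` is a dataset.
#' @return An object of class `lpi_index`: list with `index` (named yearly
#'   values, base = 1), `lambda`, `method`, `n_species`, `n_populations`,
#'   `pop_method`, `window`.
#' @export
assemble_lpi_u <- function(d, order = c("systems_within_zone",
                                        "zones_within_system"), ...) {
  order <- match.arg(order)
  pl <- .as_pop_lambdas(d, ...)
  sm <- .species_matrices(pl, c("zone", "system"))
  .finish_index(.build_lambda(sm, "U", order = order), pl, "U")
}

#' Assemble the diversity-weighted index (LPI-D)
#'
#' Species trends are averaged within each system-realm-taxon group;
#' taxon trends are combined within each realm using the taxon's share of
#' known species in that realm; realm trends are combined within each
#' system using the realm's share of known species in that system; the
#' three system trends are averaged (equally by default); and the averaged
#' rates are converted to an index with baseline 1. Every group present in
#' the data must resolve to a weight, otherwise an error lists the missing
#' keys.
#'
#' @param d An [lpd_dataset()] or a precomputed [population_lambdas()].
#' @param weights A [weight_scheme()].
#' @param ... Passed to [population_lambdas()] when `d` is a dataset.
#' @return An `lpi_index` object; see [assemble_lpi_u()].
#' @export
assemble_lpi_d <- function(d, weights, ...) {
  stopifnot(inherits(weights, "weight_scheme"))
  pl <- .as_pop_lambdas(d, ...)
  sm <- .species_matrices(pl, c("system", "realm", "taxonomic_group"))
  .finish_index(.build_lambda(sm, "D", w = weights), pl, "D")
}

#' Remove groups with low species representation
#'
#' Drops every population belonging to a system-realm-taxon group whose
#' representation fraction (species in the dataset over known species) is
#' below the threshold. Used to test the sensitivity of an index to groups
#' the database barely covers (below 1% by default).
#'
#' @param d An [lpd_dataset()].
#' @param rep Data frame with columns `system`, `realm`, `taxonomic_group`
#'   and `fraction` — typically a [representation_table()] result.
#' @param threshold Representation fraction below which a group is removed.
#' @return Filtered [lpd_dataset()] with attribute `removed_groups` (data
#'   frame of the removed keys).
#' @export
exclude_low_representation <- function(d, rep, threshold = 0.01) {
  stopifnot(inherits(d, "lpd_dataset"))
  need <- c("system", "realm", "taxonomic_group", "fraction")
  if (!all(need %in% names(rep)))
    stop("rep must have columns: ", paste(need, collapse = ", "))
  dk <- paste(d$records$system, d$records$realm, d$records$taxonomic_group)
  rk <- paste(rep$system, rep$realm, rep$taxonomic_group)
  i <- match(dk, rk)
  if (anyNA(i))
    stop("groups absent from representation table: ",
         paste(unique(dk[is.na(i)]), collapse = "; "))
  low <- rep$fraction[i] < threshold
  removed <- unique(d$records[low, c("system", "realm", "taxonomic_group")])
  rownames(removed) <- NULL
  if (all(low)) warning("all groups below representation threshold; ",
                        "empty dataset returned", call. = FALSE)
  out <- structure(list(records = d$records[!low, , drop = FALSE],
                        series = d$series[!low],
                        window = d$window), class = "lpd_dataset")
  rownames(out$records) <- NULL
  attr(out, "removed_groups") <- removed
  out
}
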