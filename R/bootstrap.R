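#' Percentile bootstrap confidence intervals for an index
#'
#' Resamples species with replacement within each lowest-level group of the
#' hierarchy (zone-by-system subsets for the unweighted index;
#' system-realm-taxon groups for the diversity-weighted index), recomputes
#' the full hierarchical aggregation for each resample, and returns per-year
#' percentile bounds. Group sizes are preserved by resampling within
#' groups, so the weights keep their meaning. The point estimate is the
#' index on the original, non-resampled data. Population-level rate
#' estimation is done once; only the species averaging upward is repeated,
#' which is what makes ten thousand iterations cheap.
#'
#' The confidence bounds inherit the baseline convention: the base year is
#' fixed at 1, so the interval has zero width there and widens as
#' uncertainty propagates through the series.
#'
#' @param d An [lpd_dataset()] or [population_lambdas()].
#' @param method `"unweighted"` or `"weighted"`.
#' @param weights A [weight_scheme()] (required for `"weighted"`).
#' @param n_iterations Number of bootstrap resamples (10000 by default).
#' @param level Confidence level (0.95 gives 2.5/97.5 percentiles).
#' @param seed Integer seed fully determining all iterations; `NULL` leaves
#'   the RNG state alone.
#' @param order Passed to [assemble_lpi_u()].
#' @param ... Passed to [population_lambdas()] when `d` is a dataset.
#' @return An `lpi_index` object with `ci_low` and `ci_high` named vectors
#'   added, plus `n_iterations` and `level`.
#' @export
bootstrap_index <- function(d, method = c("unweighted", "weighted"),
                            weights = NULL, n_iterations = 10000L,
                            level = 0.95, seed = NULL,
                            order = c("systems_within_zone",
                                      "zones_within_system"), ...) {
  method <- match.arg(method)
  order <- match.arg(order)
  stopifnot(n_iterations >= 1, level > 0, level < 1)
  type <- if (method == "weighted") "D" else "U"
  if (type == "D" && !inherits(weights, "weight_scheme"))
    stop("weighted method requires a weight_scheme")
  pl <- .as_pop_lambdas(d, ...)
  by <- if (type == "U") c("zone", "system")
        else c("system", "realm", "taxonomic_group")
  sm <- .species_matrices(pl, by)
  point <- .finish_index(.build_lambda(sm, type, w = weights, order = order),
                         pl, type)

  sizes <- vapply(sm$mats, nrow, integer(1))
  if (any(sizes == 1L))
    message(sum(sizes == 1L),
            " group(s) with a single species: resampling is degenerate there")
  if (!is.null(seed)) set.seed(seed)
  yrs <- names(point$index)
  boot <- matrix(NA_real_, n_iterations, length(yrs),
                 dimnames = list(NULL, yrs))
  for (b in seq_len(n_iterations)) {
    idx <- lapply(sizes, function(n) sample.int(n, n, replace = TRUE))
    lam <- .build_lambda(sm, type, w = weights, order = order, idx = idx)
    lam[is.na(lam)] <- 0
    boot[b, ] <- lambdas_to_index(lam, pl$window[1])
  }
  a <- (1 - level) / 2
  point$ci_low <- apply(boot, 2, stats::quantile, probs = a, names = FALSE)
  point$ci_high <- apply(boot, 2, stats::quantile, probs = 1 - a,
                         names = FALSE)
  names(point$ci_low) <- names(point$ci_high) <- yrs
  point$n_iterations <- n_iterations
  point$level <- level
  point
}
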