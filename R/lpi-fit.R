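#' Fit a multi-species abundance index
#'
#' The main entry point. Takes a population dataset (or a path to an
#' LPD-style CSV), estimates every population's annual log10 rates of
#' change (GAM smoothing for series with at least `gam_min_points`
#' observations, chain method otherwise), averages rates within species,
#' aggregates species trends through the chosen hierarchy, and converts
#' the averaged rates to an index with value 1 in the base year.
#' Optionally attaches percentile bootstrap confidence intervals from
#' species resampling.
#'
#' @param data An [lpd_dataset()] or a file path readable by
#'   [read_population_table()].
#' @param method `"unweighted"` (zone-by-system hierarchy, all levels
#'   equally weighted) or `"weighted"` (taxa weighted by share of known
#'   species within realm, realms by share within system, systems equal).
#' @param weights A [weight_scheme()] or path to one; required when
#'   `method = "weighted"`.
#' @param window Index window `c(base_year, final_year)`; defaults to the
#'   dataset's window (1970–2012 for freshly read tables).
#' @param cap Symmetric clip bound on annual rates, log10 units per year
#'   (`Inf` disables).
#' @param gam_min_points Minimum observations for the GAM route.
#' @param boot Number of bootstrap iterations; 0 skips the bootstrap.
#' @param level Confidence level for bootstrap intervals.
#' @param seed Integer seed for the bootstrap.
#' @param order Averaging order for the unweighted hierarchy; see
#'   [assemble_lpi_u()].
#' @return An object of class `lpi` (also `lpi_index`) with components
#'   `index`, `lambda`, `ci_low`/`ci_high` (when bootstrapped), `method`,
#'   `n_species`, `n_populations`, `pop_method`, `window`, `call`.
#' @examples
#' sim <- simulate_lpd(sim_config(
#'   groups = data.frame(system = "terrestrial", realm = "Palearctic",
#'                       taxonomic_group = c("Birds", "Mammals"),
#'                       zone = "temperate", rate = c(1.01, 0.97),
#'                       n_species = 5, n_pops = 2),
#'   seed = 7))
#' fit <- lpi(sim$dataset, method = "unweighted")
#' summary(fit)
#' @export
lpi <- function(data, method = c("unweighted", "weighted"), weights = NULL,
                window = NULL, cap = 1, gam_min_points = 6L,
                boot = 0L, level = 0.95, seed = NULL,
                order = c("systems_within_zone", "zones_within_system")) {
  cl <- match.call()
  method <- match.arg(method)
  order <- match.arg(order)
  if (is.character(data))
    data <- read_population_table(data,
                                  window = if (is.null(window))
                                    c(1970L, 2012L) else window)
  stopifnot(inherits(data, "lpd_dataset"))
  if (!is.null(window) && !identical(as.integer(window), data$window))
    data <- truncate_window(data, window)
  if (method == "weighted") {
    if (is.character(weights)) weights <- read_weight_scheme(weights)
    if (!inherits(weights, "weight_scheme"))
      stop("method = \"weighted\" requires a weight_scheme ",
           "(object or file path)")
  }
  pl <- population_lambdas(data, cap = cap, gam_min_points = gam_min_points)
  fit <- if (boot > 0) {
    bootstrap_index(pl, method = method, weights = weights,
                    n_iterations = boot, level = level, seed = seed,
                    order = order)
  } else if (method == "weighted") {
    assemble_lpi_d(pl, weights)
  } else {
    assemble_lpi_u(pl, order = order)
  }
  fit$call <- cl
  class(fit) <- c("lpi", class(fit))
  fit
}

#' @export
print.lpi <- function(x, ...) {
  lab <- if (x$method == "D") "diversity-weighted (LPI-D)"
         else "unweighted (LPI-U)"
  cat("Multi-species abundance index,", lab, "\n")
  cat(sprintf("  window %d-%d | %d species, %d populations\n",
              x$window[1], x$window[2], x$n_species, x$n_populations))
  fin <- unname(x$index[length(x$index)])
  cat(sprintf("  final index: %.3f (%+.1f%% overall", fin,
              100 * (fin - 1)))
  if (!is.null(x$ci_low))
    cat(sprintf("; %g%% CI %.3f-%.3f", 100 * x$level,
                x$ci_low[length(x$ci_low)], x$ci_high[length(x$ci_high)]))
  cat(")\n")
  invisible(x)
}

#' @rdname lpi
#' @param object,x An `lpi` fit.
#' @param ... Unused.
#' @export
summary.lpi <- function(object, ...) {
  x <- object
  n_years <- x$window[2] - x$window[1]
  fin <- unname(x$index[length(x$index)])
  out <- list(method = x$method, window = x$window,
              n_species = x$n_species, n_populations = x$n_populations,
              pop_method = x$pop_method, n_clipped = x$n_clipped,
              final_index = fin,
              change_pct = 100 * (fin - 1),
              annual_change_pct = -annualized_rate(fin, n_years),
              ci = if (!is.null(x$ci_low))
                c(low = unname(x$ci_low[length(x$ci_low)]),
                  high = unname(x$ci_high[length(x$ci_high)])),
              level = x$level, n_iterations = x$n_iterations)
  class(out) <- "summary.lpi"
  out
}

#' @export
print.summary.lpi <- function(x, ...) {
  lab <- if (x$method == "D") "diversity-weighted (LPI-D)"
         else "unweighted (LPI-U)"
  cat("Multi-species abundance index,", lab, "\n")
  cat(sprintf("Window: %d-%d (%d years)\n", x$window[1], x$window[2],
              x$window[2] - x$window[1]))
  cat(sprintf("Data: %d species, %d populations (%s)\n",
              x$n_species, x$n_populations,
              paste(sprintf("%s: %d", names(x$pop_method), x$pop_method),
                    collapse = ", ")))
  if (isTRUE(x$n_clipped > 0))
    cat(sprintf("Clipped annual rates: %d\n", x$n_clipped))
  cat(sprintf("Final index: %.3f (overall change %+.1f%%)\n",
              x$final_index, x$change_pct))
  cat(sprintf("Average annual change: %+.2f%% per year\n",
              x$annual_change_pct))
  if (!is.null(x$ci))
    cat(sprintf("%g%% CI for final index: %.3f-%.3f (%d bootstrap iterations)\n",
                100 * x$level, x$ci["low"], x$ci["high"], x$n_iterations))
  invisible(x)
}

#' @rdname lpi
#' @export
coef.lpi <- function(object, ...) {
  n_years <- object$window[2] - object$window[1]
  fin <- unname(object$index[length(object$index)])
  c(final_index = fin,
    change_pct = 100 * (fin - 1),
    annual_change_pct = -annualized_rate(fin, n_years))
}

#' @rdname lpi
#' @export
as.data.frame.lpi <- function(x, ...) {
  data.frame(year = as.integer(names(x$index)),
             index = unname(x$index),
             ci_low = if (is.null(x$ci_low)) NA_real_ else unname(x$ci_low),
             ci_high = if (is.null(x$ci_high)) NA_real_
                       else unname(x$ci_high))
}

#' Plot an index trajectory with its confidence band
#'
#' Base-graphics plot of the index against year; when bootstrap bounds are
#' present they are drawn as a shaded band.
#'
#' @param x An `lpi` fit.
#' @param col Line colour.
#' @param ci_col Band colour.
#' @param ... Further arguments to [graphics::plot()].
#' @export
plot.lpi <- function(x, col = "darkgreen",
                     ci_col = grDevices::adjustcolor(col, 0.25), ...) {
  yrs <- as.integer(names(x$index))
  ylim <- range(c(x$index, x$ci_low, x$ci_high), na.rm = TRUE)
  graphics::plot(yrs, x$index, type = "n", xlab = "Year",
                 ylab = sprintf("Index (%d = 1)", x$window[1]),
                 ylim = ylim, ...)
  if (!is.null(x$ci_low))
    graphics::polygon(c(yrs, rev(yrs)), c(x$ci_low, rev(x$ci_high)),
                      col = ci_col, border = NA)
  graphics::lines(yrs, x$index, col = col, lwd = 2)
  graphics::abline(h = 1, lty = 3, col = "grey40")
  invisible(x)
}

#' Write index results to CSV
#'
#' One row per year with columns `year`, `index`, `ci_low`, `ci_high`.
#'
#' @param x An `lpi` or `lpi_index` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index_csv <- function(x, path) {
  df <- data.frame(year = as.integer(names(x$index)),
                   index = unname(x$index),
                   ci_low = if (is.null(x$ci_low)) NA_real_
                            else unname(x$ci_low),
                   ci_high = if (is.null(x$ci_high)) NA_real_
                             else unname(x$ci_high))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
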