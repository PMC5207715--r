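#' Zero-adjust an abundance series
#'
#' The annual rate of change is a log ratio and is undefined at zero
#' abundance. When a series contains any zero observation, a constant equal
#' to 1% of the mean of the observed values is added to every observation;
#' otherwise the series is returned unchanged. An all-zero series carries no
#' trend information and is flagged by returning `NULL` with a warning so
#' the caller can drop it.
#'
#' @param x Named numeric vector (names are years), values >= 0.
#' @return Adjusted series, or `NULL` for an all-zero series.
#' @export
zero_adjust <- function(x) {
  if (!length(x)) stop("empty series")
  if (any(x < 0)) stop("negative abundance")
  if (!any(x == 0)) return(x)
  m <- mean(x)
  if (m == 0) {
    warning("all-zero series dropped", call. = FALSE)
    return(NULL)
  }
  x + 0.01 * m
}

#' Log-linear interpolation of a sparse abundance series
#'
#' Fills every interior year between the first and last observation by
#' linear interpolation of log10 abundance between the flanking
#' observations (so a gap is bridged at a constant multiplicative rate).
#' Observed endpoints are unchanged and no extrapolation is performed. This
#' is the completion step of the chain method.
#'
#' @param x Named numeric vector, all values > 0, at least two observations.
#' @return Named numeric vector covering every year from first to last
#'   observation.
#' @export
interpolate_log_linear <- function(x) {
  if (length(x) < 2L) stop("need at least 2 observations")
  if (any(x <= 0)) stop("non-positive abundance; zero-adjust first")
  yrs <- as.integer(names(x))
  o <- order(yrs)
  yrs <- yrs[o]; x <- x[o]
  full <- seq(yrs[1], yrs[length(yrs)])
  out <- 10^stats::approx(yrs, log10(x), xout = full)$y
  names(out) <- full
  out[as.character(yrs)] <- x  # exact at observed years
  out
}

#' GAM smooth of an abundance series
#'
#' Fits a penalized regression spline of log10 abundance against year
#' (basis dimension half the number of observations, minimum 3) and
#' evaluates the smooth at every year from the first to the last
#' observation. Used for series with at least `min_points` observations;
#' shorter series fall back to the chain method.
#'
#' A fit is reported as failed (`ok = FALSE`) when the model errors, any
#' fitted value is non-finite, or the fitted log10 abundance leaves the
#' observed range by more than one order of magnitude — a conservative
#' screen for degenerate smooths.
#'
#' @param x Named numeric vector, values > 0 (zero-adjust first).
#' @param min_points Minimum number of observations for the GAM route.
#' @return List with `fitted` (named vector of fitted abundances over the
#'   full span, or `NULL`) and `ok` (logical).
#' @export
fit_gam_trend <- function(x, min_points = 6L) {
  yrs <- as.integer(names(x))
  o <- order(yrs); yrs <- yrs[o]; x <- x[o]
  if (length(x) < min_points) return(list(fitted = NULL, ok = FALSE))
  if (any(x <= 0)) stop("non-positive abundance; zero-adjust first")
  ly <- log10(x)
  k <- min(length(x), max(3L, ceiling(length(x) / 2)))
  full <- seq(yrs[1], yrs[length(yrs)])
  fit <- tryCatch({
    m <- mgcv::gam(ly ~ s(year, k = k),
                   data = data.frame(ly = ly, year = yrs))
    as.numeric(stats::predict(m, newdata = data.frame(year = full)))
  }, error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit)) ||
      max(fit) > max(ly) + 1 || min(fit) < min(ly) - 1)
    return(list(fitted = NULL, ok = FALSE))
  list(fitted = stats::setNames(10^fit, full), ok = TRUE)
}

#' Annual log10 rates of change of a complete series
#'
#' For a series observed (or smoothed/interpolated) in every consecutive
#' year, the rate for year t is `log10(N_t / N_(t-1))`.
#'
#' @param x Named numeric vector over consecutive years, all values > 0.
#' @return Named numeric vector of rates for the second year onward.
#' @export
series_lambdas <- function(x) {
  yrs <- as.integer(names(x))
  if (length(x) < 2L) stop("need at least 2 values")
  if (any(diff(yrs) != 1L)) stop("years must be consecutive")
  if (any(x <= 0)) stop("non-positive abundance; zero-adjust first")
  stats::setNames(diff(log10(x)), yrs[-1])
}

#' Clip annual rates to a symmetric cap
#'
#' Guards the species averages against extreme single-year rates (for
#' example a census resuming after a crash). The default of one log10 unit
#' per year allows up to a tenfold change; `cap = Inf` disables clipping.
#' The number of clipped values is recorded in the `"n_clipped"` attribute.
#'
#' @param l Named numeric vector of annual log10 rates.
#' @param cap Positive clip bound in log10 units per year.
#' @return Clipped rates with attribute `n_clipped`.
#' @export
cap_lambdas <- function(l, cap = 1) {
  if (!is.numeric(cap) || cap <= 0) stop("cap must be positive")
  n <- sum(abs(l) > cap, na.rm = TRUE)
  out <- pmin(pmax(l, -cap), cap)
  attr(out, "n_clipped") <- n
  out
}

# one population: sparse series -> annual rates over its span.
# GAM route for >= min_points observations, chain method otherwise or on a
# poor fit. Returns NULL (dropped) for all-zero series.
.population_lambdas_one <- function(x, cap = 1, gam_min_points = 6L,
                                    method = c("auto", "chain", "gam")) {
  method <- match.arg(method)
  x <- zero_adjust(x)
  if (is.null(x)) return(NULL)
  used <- "chain"
  fitted <- NULL
  if (method != "chain") {
    g <- fit_gam_trend(x, min_points = gam_min_points)
    if (g$ok) { fitted <- g$fitted; used <- "gam" }
    else if (method == "gam") return(NULL)
  }
  if (is.null(fitted)) fitted <- interpolate_log_linear(x)
  lam <- cap_lambdas(series_lambdas(fitted), cap = cap)
  list(lambdas = lam, method = used,
       n_clipped = attr(lam, "n_clipped"))
}

#' Annual rates of change for every population in a dataset
#'
#' Converts each population's sparse series into annual log10 rates
#' (GAM smoothing for series with at least `gam_min_points` observations,
#' chain method otherwise), clips them at `cap`, and arranges them in a
#' populations-by-years matrix aligned on the dataset window. Years outside
#' a population's observed span are `NA`.
#'
#' @param d An [lpd_dataset()].
#' @inheritParams cap_lambdas
#' @param gam_min_points Minimum observations for the GAM route.
#' @param method `"auto"` (default: GAM where eligible, chain fallback),
#'   `"chain"`, or `"gam"` (GAM only; ineligible populations dropped).
#' @return List of class `population_lambdas`: `lambda` (matrix, rownames
#'   population ids, colnames years `base+1 .. final`), `records` (metadata
#'   of retained populations), `method` (per-population `"gam"`/`"chain"`),
#'   `n_clipped` (total clipped rates), `window`.
#' @export
population_lambdas <- function(d, cap = 1, gam_min_points = 6L,
                               method = c("auto", "chain", "gam")) {
  stopifnot(inherits(d, "lpd_dataset"))
  method <- match.arg(method)
  yrs <- seq(d$window[1] + 1L, d$window[2])
  n <- nrow(d$records)
  lam <- matrix(NA_real_, n, length(yrs),
                dimnames = list(d$records$population_id, yrs))
  used <- character(n); clipped <- 0L; keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    res <- .population_lambdas_one(d$series[[i]], cap = cap,
                                   gam_min_points = gam_min_points,
                                   method = method)
    if (is.null(res)) { keep[i] <- FALSE; next }
    lam[i, names(res$lambdas)] <- res$lambdas
    used[i] <- res$method
    clipped <- clipped + res$n_clipped
  }
  structure(list(lambda = lam[keep, , drop = FALSE],
                 records = d$records[keep, , drop = FALSE],
                 method = used[keep], n_clipped = clipped,
                 window = d$window),
            class = "population_lambdas")
}

#' Average population rates within a species
#'
#' For each year, the species trend is the arithmetic mean of the annual
#' log10 rates over the populations that have a rate in that year, so
#' populations enter and leave the average as their series start and end.
#'
#' @param pops List of named numeric vectors (one per population, names are
#'   years) or a matrix with populations in rows and years in columns.
#' @return List with `lambda` (named vector of per-year means) and `n`
#'   (named integer vector, populations contributing per year).
#' @export
species_mean_lambdas <- function(pops) {
  if (is.matrix(pops)) m <- pops
  else {
    if (!length(pops)) stop("no population series")
    yrs <- sort(unique(unlist(lapply(pops, names))))
    m <- matrix(NA_real_, length(pops), length(yrs),
                dimnames = list(NULL, yrs))
    for (i in seq_along(pops)) m[i, names(pops[[i]])] <- pops[[i]]
  }
  if (!nrow(m)) stop("no population series")
  n <- colSums(!is.na(m))
  lam <- colMeans(m, na.rm = TRUE)
  lam[n == 0L] <- NA_real_
  list(lambda = lam, n = n)
}
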