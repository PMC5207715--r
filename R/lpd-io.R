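#' Default taxonomic class-to-group mapping
#'
#' Maps raw taxonomic class labels to the four analysis groups. Reptiles and
#' amphibians are pooled into a single herpetofauna group ("Herps") because
#' both are sparsely monitored; fishes of all classes map to "Fish".
#'
#' @return Named character vector: names are raw class labels (case
#'   insensitive on use), values are analysis groups
#'   (Birds, Mammals, Fish, Herps).
#' @export
default_class_map <- function() {
  c(Aves = "Birds", Birds = "Birds",
    Mammalia = "Mammals", Mammals = "Mammals",
    Reptilia = "Herps", Amphibia = "Herps", Reptiles = "Herps",
    Amphibians = "Herps", Herps = "Herps",
    Actinopterygii = "Fish", Chondrichthyes = "Fish",
    Sarcopterygii = "Fish", Cephalaspidomorphi = "Fish",
    Myxini = "Fish", Pisces = "Fish", Fish = "Fish", Fishes = "Fish")
}

#' Default biogeographic realm merges
#'
#' Australasia, Oceania and Indo-Malaya are merged into a single
#' "Indo-Pacific" realm for land and freshwater populations; all other realm
#' labels pass through unchanged.
#'
#' @return Named character vector mapping raw realm labels to merged labels.
#' @export
default_realm_map <- function() {
  c(Australasia = "Indo-Pacific", Oceania = "Indo-Pacific",
    `Indo-Malaya` = "Indo-Pacific", `Indo-Pacific` = "Indo-Pacific")
}

.systems <- c("terrestrial", "freshwater", "marine")
.zones <- c("tropical", "temperate")

.apply_map <- function(x, map) {
  hit <- match(tolower(x), tolower(names(map)))
  out <- ifelse(is.na(hit), x, unname(map[hit]))
  out
}

#' Construct a population dataset
#'
#' Low-level constructor used by [read_population_table()] and
#' [simulate_lpd()]. Validates record metadata and the sparse abundance
#' series, truncates series to the index window, and enforces the rule that
#' every retained population has at least two observed years.
#'
#' @param records Data frame with columns `population_id`,
#'   `species_binomial`, `taxonomic_group`, `system`, `realm`, `zone`, and
#'   optionally `units`, `source_id`, `confidential`.
#' @param series Named list (by `population_id`) of named numeric vectors;
#'   vector names are calendar years, values are non-negative abundances in
#'   arbitrary units.
#' @param window Integer vector `c(base_year, final_year)` delimiting the
#'   index period.
#' @param drop_invalid Drop records violating the invariants with a warning
#'   (default) instead of erroring.
#' @return An object of class `lpd_dataset`: a list with elements `records`,
#'   `series` and `window`.
#' @export
lpd_dataset <- function(records, series, window = c(1970L, 2012L),
                        drop_invalid = TRUE) {
  window <- as.integer(window)
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be c(base_year, final_year) with base < final")
  need <- c("population_id", "species_binomial", "taxonomic_group",
            "system", "realm", "zone")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records is missing columns: ", paste(miss, collapse = ", "))
  records$population_id <- as.character(records$population_id)
  if (anyDuplicated(records$population_id))
    stop("duplicate population_id values")
  if (is.null(records$units)) records$units <- ""
  if (is.null(records$source_id)) records$source_id <- ""
  if (is.null(records$confidential)) records$confidential <- FALSE
  records$system <- tolower(as.character(records$system))
  records$zone <- tolower(as.character(records$zone))
  bad_sys <- !records$system %in% .systems
  bad_zone <- !records$zone %in% .zones
  if (any(bad_sys))
    stop("unknown system: ", paste(unique(records$system[bad_sys]),
                                   collapse = ", "))
  if (any(bad_zone))
    stop("unknown zone: ", paste(unique(records$zone[bad_zone]),
                                 collapse = ", "))

  series <- series[records$population_id]
  keep <- rep(TRUE, nrow(records))
  why <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    x <- series[[i]]
    if (is.null(x) || !length(x)) { keep[i] <- FALSE; why[i] <- "no observations"; next }
    yrs <- as.integer(names(x))
    if (anyNA(yrs)) stop("non-integer year labels for population ",
                         records$population_id[i])
    inw <- yrs >= window[1] & yrs <= window[2]
    x <- x[inw]
    if (any(x < 0, na.rm = TRUE)) { keep[i] <- FALSE; why[i] <- "negative abundance"; next }
    x <- x[!is.na(x)]
    if (length(x) < 2L) { keep[i] <- FALSE; why[i] <- "fewer than 2 observed years in window"; next }
    series[[i]] <- x[order(as.integer(names(x)))]
  }
  if (any(!keep)) {
    msg <- paste0(records$population_id[!keep], " (", why[!keep], ")")
    if (!drop_invalid)
      stop("invalid records: ", paste(msg, collapse = "; "))
    warning("dropping ", sum(!keep), " record(s): ",
            paste(msg, collapse = "; "), call. = FALSE)
    records <- records[keep, , drop = FALSE]
    series <- series[keep]
    rownames(records) <- NULL
  }
  structure(list(records = records, series = series, window = window),
            class = "lpd_dataset")
}

#' @export
print.lpd_dataset <- function(x, ...) {
  cat("<lpd_dataset> ", nrow(x$records), " populations, ",
      length(unique(x$records$species_binomial)), " species, window ",
      x$window[1], "-", x$window[2], "\n", sep = "")
  tab <- table(x$records$system, x$records$taxonomic_group)
  print(tab)
  invisible(x)
}

#' Read an LPD-style wide population table
#'
#' Parses a CSV with fixed metadata columns (`ID`, `Binomial`, `Class`,
#' `System`, `Realm`, `Zone`, `Units`, `Source`, `Confidential`) followed by
#' one column per calendar year. Missing abundances are encoded `NULL`,
#' `NA`, or an empty cell. Raw taxonomic classes and realms are mapped to
#' analysis groups at read time, so the raw file stays unmodified and the
#' merges stay auditable.
#'
#' Records with fewer than two observed years inside the window (after
#' truncation) are excluded with a warning naming the population; a zero
#' abundance is a valid observation and is retained (zero handling happens
#' downstream in [zero_adjust()]).
#'
#' @param path Path to the CSV file.
#' @param window Index window `c(base_year, final_year)`; observations
#'   outside it are discarded before the two-observation rule is re-checked.
#' @param class_map,realm_map Named character vectors applied to the raw
#'   `Class` and `Realm` columns; see [default_class_map()] and
#'   [default_realm_map()].
#' @return An [lpd_dataset()].
#' @export
read_population_table <- function(path, window = c(1970L, 2012L),
                                  class_map = default_class_map(),
                                  realm_map = default_realm_map()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  meta_cols <- c("ID", "Binomial", "Class", "System", "Realm", "Zone",
                 "Units", "Source", "Confidential")
  miss <- setdiff(c("ID", "Binomial", "Class", "System", "Realm", "Zone"),
                  names(raw))
  if (length(miss))
    stop("malformed header: missing column(s) ", paste(miss, collapse = ", "))
  year_cols <- setdiff(names(raw), meta_cols)
  yrs <- suppressWarnings(as.integer(year_cols))
  if (anyNA(yrs))
    stop("malformed header: non-year column(s) ",
         paste(year_cols[is.na(yrs)], collapse = ", "))
  ord <- order(yrs)
  year_cols <- year_cols[ord]; yrs <- yrs[ord]

  parse_cell <- function(v) {
    v <- trimws(v)
    v[v %in% c("NULL", "", "NA")] <- NA
    suppressWarnings(as.numeric(v))
  }
  series <- lapply(seq_len(nrow(raw)), function(i) {
    vals <- parse_cell(unlist(raw[i, year_cols], use.names = FALSE))
    names(vals) <- yrs
    vals[!is.na(vals)]
  })
  names(series) <- raw$ID
  records <- data.frame(
    population_id = raw$ID,
    species_binomial = raw$Binomial,
    taxonomic_group = .apply_map(raw$Class, class_map),
    system = raw$System,
    realm = .apply_map(raw$Realm, realm_map),
    zone = raw$Zone,
    units = if ("Units" %in% names(raw)) raw$Units else "",
    source_id = if ("Source" %in% names(raw)) raw$Source else "",
    confidential = if ("Confidential" %in% names(raw))
      tolower(raw$Confidential) %in% c("true", "1", "yes") else FALSE,
    stringsAsFactors = FALSE)
  lpd_dataset(records, series, window = window)
}

#' Write a population dataset back to the wide CSV dialect
#'
#' Inverse of [read_population_table()] up to the class/realm merges:
#' observed values are written as numbers, unobserved years as `NULL`.
#'
#' @param d An [lpd_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_table <- function(d, path) {
  stopifnot(inherits(d, "lpd_dataset"))
  yrs <- seq(d$window[1], d$window[2])
  mat <- matrix("NULL", nrow(d$records), length(yrs),
                dimnames = list(NULL, yrs))
  for (i in seq_along(d$series)) {
    x <- d$series[[i]]
    mat[i, names(x)] <- format(unname(x), trim = TRUE, scientific = FALSE,
                               digits = 15)
  }
  out <- data.frame(ID = d$records$population_id,
                    Binomial = d$records$species_binomial,
                    Class = d$records$taxonomic_group,
                    System = d$records$system,
                    Realm = d$records$realm,
                    Zone = d$records$zone,
                    Units = d$records$units,
                    Source = d$records$source_id,
                    Confidential = d$records$confidential,
                    mat, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Restrict a dataset to a new index window
#'
#' Truncates every series to the window and re-applies the two-observation
#' rule; populations left with fewer than two observations are dropped with
#' a warning.
#'
#' @param d An [lpd_dataset()].
#' @param window `c(base_year, final_year)`.
#' @return An [lpd_dataset()] with the new window.
#' @export
truncate_window <- function(d, window) {
  stopifnot(inherits(d, "lpd_dataset"))
  lpd_dataset(d$records, d$series, window = window)
}
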