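#' Construct a hierarchical weight scheme
#'
#' A weight scheme holds the three levels of proportional weights used by
#' the diversity-weighted index: systems (weighted equally by convention,
#' but configurable), realms within each system (each realm's share of the
#' known species in that system), and taxonomic groups within each
#' realm-system combination (each group's share of the known species in
#' that realm). Weights are renormalized to sum to one within each parent;
#' raw known-species counts may be supplied instead of proportions.
#'
#' @param taxon Data frame with columns `system`, `realm`, `taxon`,
#'   `weight`, and optionally `known_species`.
#' @param realm Data frame with columns `system`, `realm`, `weight`.
#' @param system Named numeric vector of system weights; default equal.
#' @return An object of class `weight_scheme`.
#' @export
weight_scheme <- function(taxon, realm,
                          system = c(terrestrial = 1, freshwater = 1,
                                     marine = 1)) {
  norm <- function(w, what) {
    if (any(!is.finite(w)) || any(w < 0))
      stop("negative or non-finite weight in ", what)
    s <- sum(w)
    if (s <= 0) stop("weights sum to zero in ", what)
    w / s
  }
  taxon <- as.data.frame(taxon, stringsAsFactors = FALSE)
  realm <- as.data.frame(realm, stringsAsFactors = FALSE)
  stopifnot(all(c("system", "realm", "taxon", "weight") %in% names(taxon)),
            all(c("system", "realm", "weight") %in% names(realm)))
  taxon$system <- tolower(taxon$system)
  realm$system <- tolower(realm$system)
  if (anyDuplicated(taxon[c("system", "realm", "taxon")]))
    stop("duplicate (system, realm, taxon) key in taxon weights")
  if (anyDuplicated(realm[c("system", "realm")]))
    stop("duplicate (system, realm) key in realm weights")
  for (key in split(seq_len(nrow(taxon)),
                    paste(taxon$system, taxon$realm, sep = "|")))
    taxon$weight[key] <- norm(taxon$weight[key],
                              paste("taxon weights of",
                                    taxon$system[key[1]], taxon$realm[key[1]]))
  for (key in split(seq_len(nrow(realm)), realm$system))
    realm$weight[key] <- norm(realm$weight[key],
                              paste("realm weights of", realm$system[key[1]]))
  system <- norm(system, "system weights")
  structure(list(system = system, realm = realm, taxon = taxon),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("<weight_scheme>\n systems:",
      paste(sprintf("%s=%.3f", names(x$system), x$system), collapse = ", "),
      "\n", nrow(x$realm), "realm weights,", nrow(x$taxon),
      "taxon weights\n")
  invisible(x)
}

#' Read a weight scheme from CSV or YAML
#'
#' The flat file lists one row per weight with columns `level`
#' (`"system"`, `"realm"` or `"taxon"`), `system`, `realm`, `taxon`,
#' `weight`, and optionally `known_species`. Weights are renormalized per
#' parent on read, so either proportions or raw species counts may be
#' supplied.
#'
#' @param path CSV (`.csv`) or YAML (`.yml`/`.yaml`) file.
#' @return A [weight_scheme()].
#' @export
read_weight_scheme <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    tab <- do.call(rbind, lapply(y, function(r)
      data.frame(level = r$level, system = r$system,
                 realm = if (is.null(r$realm)) NA else r$realm,
                 taxon = if (is.null(r$taxon)) NA else r$taxon,
                 weight = r$weight,
                 known_species = if (is.null(r$known_species)) NA
                                 else r$known_species,
                 stringsAsFactors = FALSE)))
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  }
  need <- c("level", "system", "weight")
  if (!all(need %in% names(tab)))
    stop("weight table must have columns: ", paste(need, collapse = ", "))
  if (is.null(tab$known_species)) tab$known_species <- NA_real_
  if (any(!is.finite(tab$weight)) || any(tab$weight < 0))
    stop("negative or non-finite weight in ", path)
  lev <- tolower(tab$level)
  tax <- tab[lev == "taxon", c("system", "realm", "taxon", "weight",
                               "known_species")]
  rlm <- tab[lev == "realm", c("system", "realm", "weight")]
  sys <- tab[lev == "system", c("system", "weight")]
  sw <- if (nrow(sys)) stats::setNames(sys$weight, tolower(sys$system))
        else c(terrestrial = 1, freshwater = 1, marine = 1)
  weight_scheme(taxon = tax, realm = rlm, system = sw)
}

# weight lookups; error listing every unresolved key so users can fix the
# scheme in one pass
.taxon_weights <- function(w, system, realm, taxa) {
  i <- match(paste(system, realm, taxa),
             paste(w$taxon$system, w$taxon$realm, w$taxon$taxon))
  if (anyNA(i))
    stop("no taxon weight for: ",
         paste(paste(system, realm, taxa)[is.na(i)], collapse = "; "))
  w$taxon$weight[i]
}

.realm_weights <- function(w, system, realms) {
  i <- match(paste(system, realms), paste(w$realm$system, w$realm$realm))
  if (anyNA(i))
    stop("no realm weight for: ",
         paste(paste(system, realms)[is.na(i)], collapse = "; "))
  w$realm$weight[i]
}
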