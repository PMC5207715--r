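.stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Two-sample test of equal proportions
#'
#' Chi-squared test on the 2x2 table of (`x1` of `n1`) versus (`x2` of
#' `n2`), with Yates continuity correction by default. The direction label
#' compares the sample proportions: `"over"` when `x1/n1 > x2/n2`,
#' otherwise `"under"` (ties count as `"under"`).
#'
#' @param x1,n1 Successes and trials in the first sample (the dataset).
#' @param x2,n2 Successes and trials in the second sample (the reference).
#' @param correct Apply the continuity correction (default `TRUE`).
#' @return List with `chi2`, `p`, `direction`.
#' @export
proportion_test <- function(x1, n1, x2, n2, correct = TRUE) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  pt <- suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), correct = correct))
  list(chi2 = unname(pt$statistic), p = unname(pt$p.value),
       direction = if (x1 / n1 > x2 / n2) "over" else "under")
}

#' Taxonomic representation of a dataset against known species counts
#'
#' For every system-realm-taxon group in the reference table, counts the
#' unique species present in the dataset, computes the representation
#' fraction (species in dataset over known species), and — within each
#' system-realm — tests whether the taxon's share of the dataset's species
#' differs from its share of the known species, labelling significant
#' groups as over- or under-represented.
#'
#' @param d An [lpd_dataset()].
#' @param reference Data frame with columns `system`, `realm`,
#'   `taxonomic_group`, `known_species`. Must cover every group present in
#'   the dataset.
#' @param correct Continuity correction for the proportion tests.
#' @return Data frame of class `representation_table` with one row per
#'   reference group: counts, proportions, `fraction`, `chi2`, `p`,
#'   `direction`, `significant`, `stars`.
#' @export
representation_table <- function(d, reference, correct = TRUE) {
  stopifnot(inherits(d, "lpd_dataset"))
  need <- c("system", "realm", "taxonomic_group", "known_species")
  if (!all(need %in% names(reference)))
    stop("reference must have columns: ", paste(need, collapse = ", "))
  reference$system <- tolower(reference$system)
  if (anyDuplicated(reference[c("system", "realm", "taxonomic_group")]))
    stop("duplicate group key in reference")
  rec <- unique(d$records[c("system", "realm", "taxonomic_group",
                            "species_binomial")])
  dk <- paste(rec$system, rec$realm, rec$taxonomic_group)
  rk <- paste(reference$system, reference$realm, reference$taxonomic_group)
  if (any(!unique(dk) %in% rk))
    stop("dataset groups missing from reference: ",
         paste(setdiff(unique(dk), rk), collapse = "; "))

  out <- reference[c("system", "realm", "taxonomic_group", "known_species")]
  out$n_in_dataset <- as.integer(table(factor(dk, levels = rk)))
  out$fraction <- out$n_in_dataset / out$known_species
  out$proportion_dataset <- NA_real_; out$proportion_reference <- NA_real_
  out$chi2 <- NA_real_; out$p <- NA_real_
  out$direction <- NA_character_
  parent <- paste(out$system, out$realm)
  for (pk in unique(parent)) {
    i <- which(parent == pk)
    n1 <- sum(out$n_in_dataset[i]); n2 <- sum(out$known_species[i])
    if (n1 == 0) next  # realm unobserved: no within-realm test possible
    for (j in i) {
      out$proportion_dataset[j] <- out$n_in_dataset[j] / n1
      out$proportion_reference[j] <- out$known_species[j] / n2
      tt <- proportion_test(out$n_in_dataset[j], n1, out$known_species[j],
                            n2, correct = correct)
      out$chi2[j] <- tt$chi2; out$p[j] <- tt$p
      out$direction[j] <- tt$direction
    }
  }
  out$significant <- !is.na(out$p) & out$p < 0.05
  out$stars <- ifelse(is.na(out$p), "", .stars(out$p))
  class(out) <- c("representation_table", "data.frame")
  out
}

.rl_categories <- c("LC", "NT/LR", "VU", "EN", "CR")
.rl_threatened <- c("VU", "EN", "CR")

#' Red List category representation of a dataset
#'
#' Compares, per taxonomic group, the proportion of a dataset's species in
#' each Red List category (LC, NT/LR, VU, EN, CR) against reference
#' proportions from assessed species, using the two-sample proportion test.
#' `NT` and `LR` labels are merged into `NT/LR`. Data Deficient, Extinct
#' and Extinct in the Wild species must be excluded upstream.
#'
#' When `criterion_a_only = TRUE`, threatened species (VU/EN/CR) not
#' flagged as assessed under the population-reduction criterion
#' (Criterion A) are dropped from the dataset side, and the reference
#' counts for threatened categories are taken from the
#' `known_criterion_a` column — so both sides compare only species whose
#' listing implies a population decline.
#'
#' @param categories Data frame with columns `species_binomial`, `taxon`,
#'   `category`, and optionally logical `criterion_a`.
#' @param reference_counts Data frame with columns `taxon`, `category`,
#'   `known_species`, and optionally `known_criterion_a`.
#' @param criterion_a_only Restrict threatened categories to Criterion A
#'   species.
#' @param correct Continuity correction for the proportion tests.
#' @return Data frame of class `representation_table` with one row per
#'   taxon-category pair.
#' @export
redlist_comparison <- function(categories, reference_counts,
                               criterion_a_only = FALSE, correct = TRUE) {
  cat_norm <- function(x) {
    x <- toupper(trimws(x))
    x[x %in% c("NT", "LR", "NT/LR", "LR/NT")] <- "NT/LR"
    x
  }
  categories$category <- cat_norm(categories$category)
  reference_counts$category <- cat_norm(reference_counts$category)
  bad <- setdiff(unique(c(categories$category, reference_counts$category)),
                 .rl_categories)
  if (length(bad))
    stop("unknown Red List category: ", paste(bad, collapse = ", "),
         " (allowed: ", paste(.rl_categories, collapse = ", "), ")")
  if (criterion_a_only) {
    if (is.null(categories$criterion_a))
      categories$criterion_a <- FALSE
    drop <- categories$category %in% .rl_threatened &
      !isTRUE_vec(categories$criterion_a)
    if (all(drop[categories$category %in% .rl_threatened]))
      warning("no Criterion A flags among threatened species; ",
              "threatened rows are empty", call. = FALSE)
    categories <- categories[!drop, , drop = FALSE]
    if (is.null(reference_counts$known_criterion_a))
      stop("criterion_a_only requires a known_criterion_a column in ",
           "reference_counts")
    thr <- reference_counts$category %in% .rl_threatened
    reference_counts$known_species[thr] <-
      reference_counts$known_criterion_a[thr]
  }
  taxa <- unique(reference_counts$taxon)
  rows <- list()
  for (tx in taxa) {
    ref <- reference_counts[reference_counts$taxon == tx, , drop = FALSE]
    obs <- categories[categories$taxon == tx, , drop = FALSE]
    n1 <- length(unique(obs$species_binomial))
    n2 <- sum(ref$known_species)
    for (cc in intersect(.rl_categories, ref$category)) {
      x1 <- length(unique(obs$species_binomial[obs$category == cc]))
      x2 <- ref$known_species[ref$category == cc][1]
      row <- data.frame(taxon = tx, category = cc,
                        n_in_dataset = x1, n_dataset_total = n1,
                        known_species = x2, known_total = n2,
                        proportion_dataset = if (n1 > 0) x1 / n1 else NA_real_,
                        proportion_reference = if (n2 > 0) x2 / n2
                                               else NA_real_,
                        chi2 = NA_real_, p = NA_real_,
                        direction = NA_character_,
                        stringsAsFactors = FALSE)
      if (n1 > 0 && n2 > 0) {
        tt <- proportion_test(x1, n1, x2, n2, correct = correct)
        row$chi2 <- tt$chi2; row$p <- tt$p; row$direction <- tt$direction
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < 0.05
  out$stars <- ifelse(is.na(out$p), "", .stars(out$p))
  class(out) <- c("representation_table", "data.frame")
  out
}

# TRUE where x is TRUE; NA treated as FALSE
isTRUE_vec <- function(x) !is.na(x) & x
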