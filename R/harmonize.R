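#' Update a base accession against the catalog
#'
#' Implements the identifier "update": secondary accessions are converted to
#' their primary accession, non-reference-taxon identifiers are removed, and
#' obsolete identifiers are removed. Every input lands in exactly one
#' outcome; nothing is an error.
#'
#' @param bases character vector of base accessions (isoforms already
#'   stripped).
#' @param catalog a `sequence_catalog`.
#' @return data.frame with columns `input`, `outcome` (one of `primary`,
#'   `secondary_mapped`, `obsolete_dropped`, `taxon_dropped`,
#'   `unknown_dropped`) and `output` (the retained primary base, `NA` when
#'   dropped).
#' @export
update_accession <- function(bases, catalog) {
  bases <- as.character(bases)
  prim <- names(catalog$records)
  taxa <- vapply(catalog$records, function(r) r$taxon, integer(1))
  ref <- catalog$reference_taxon

  outcome <- character(length(bases))
  output <- rep(NA_character_, length(bases))
  for (i in seq_along(bases)) {
    b <- bases[i]
    if (b %in% prim) {
      if (taxa[[b]] == ref) {
        outcome[i] <- "primary"; output[i] <- b
      } else {
        outcome[i] <- "taxon_dropped"
      }
    } else if (b %in% names(catalog$secondary_to_primary)) {
      target <- catalog$secondary_to_primary[[b]]
      if (taxa[[target]] == ref) {
        outcome[i] <- "secondary_mapped"; output[i] <- target
      } else {
        outcome[i] <- "taxon_dropped"
      }
    } else if (b %in% catalog$obsolete) {
      outcome[i] <- "obsolete_dropped"
    } else {
      outcome[i] <- "unknown_dropped"
    }
  }
  data.frame(input = bases, outcome = outcome, output = output,
             stringsAsFactors = FALSE)
}

#' Resolve an ambiguous foreign-identifier mapping to one accession
#'
#' When a non-UniProt identifier maps to several candidate accessions, a
#' single one is selected to keep the mapping one-to-one: the reviewed
#' subset is preferred when non-empty, then the candidate with the longest
#' canonical sequence; remaining ties break to the lexicographically
#' smallest base, so the choice is deterministic across runs.
#'
#' @param candidates character vector of primary base accessions present in
#'   the catalog.
#' @param catalog a `sequence_catalog`.
#' @return a single base accession, or `NA_character_` for an empty
#'   candidate set.
#' @export
resolve_foreign_id <- function(candidates, catalog) {
  candidates <- unique(as.character(candidates))
  if (!length(candidates)) return(NA_character_)
  unknown <- setdiff(candidates, names(catalog$records))
  if (length(unknown)) {
    stop("candidate accessions not in catalog: ", paste(unknown, collapse = ", "))
  }
  recs <- catalog$records[candidates]
  reviewed <- vapply(recs, function(r) r$reviewed, logical(1))
  pool <- if (any(reviewed)) candidates[reviewed] else candidates
  len <- vapply(catalog$records[pool], function(r) nchar(r$canonical),
                integer(1))
  pool <- pool[len == max(len)]
  sort(pool)[1]
}

#' Harmonize one resource's annotation set to the reference catalog
#'
#' Isoform suffixes are stripped first (secondary/obsolete status is defined
#' on base accessions), then every distinct base is updated with
#' [update_accession()]. Proteins and site accessions are rewritten to their
#' retained primaries; sites whose accession is dropped are dropped with it.
#' Site positions are not renumbered when an isoform annotation is
#' reassigned to its base; any coordinate damage this causes is surfaced
#' later by the consistency classification as a mismatch or offset.
#'
#' @param raw an `annotation_set`.
#' @param catalog a `sequence_catalog`.
#' @return a list with elements `set` (the harmonized `annotation_set`) and
#'   `report` (a `harmonization_report`: per-input `outcomes` table, `kept`
#'   output bases, `mapped_secondary` map, the three `dropped_*` sets and
#'   the `isoforms_stripped` count).
#' @export
harmonize_annotation_set <- function(raw, catalog) {
  prot_in <- raw$proteins
  site_in <- raw$sites

  all_ids <- c(prot_in, site_in$accession)
  n_iso <- length(unique(all_ids[grepl("-[0-9]+$", all_ids)]))

  prot_base <- strip_isoform(prot_in)
  site_base <- strip_isoform(site_in$accession)

  inputs <- sort(unique(c(prot_base, site_base)))
  outcomes <- update_accession(inputs, catalog)
  out_map <- structure(outcomes$output, names = outcomes$input)

  new_prot <- out_map[prot_base]
  new_prot <- new_prot[!is.na(new_prot)]

  new_site_acc <- out_map[site_base]
  keep <- !is.na(new_site_acc)
  sites <- site_in[keep, , drop = FALSE]
  if (nrow(sites)) sites$accession <- unname(new_site_acc[keep])

  sec <- outcomes[outcomes$outcome == "secondary_mapped", , drop = FALSE]
  report <- structure(list(
    outcomes = outcomes,
    kept = sort(unique(outcomes$output[!is.na(outcomes$output)])),
    mapped_secondary = structure(sec$output, names = sec$input),
    dropped_obsolete = outcomes$input[outcomes$outcome == "obsolete_dropped"],
    dropped_taxon = outcomes$input[outcomes$outcome == "taxon_dropped"],
    dropped_unmappable = outcomes$input[outcomes$outcome == "unknown_dropped"],
    isoforms_stripped = n_iso), class = "harmonization_report")

  list(set = annotation_set(raw$name, proteins = unname(new_prot),
                            sites = site_table(sites$accession, sites$residue,
                                               sites$position)),
       report = report)
}

#' @export
print.harmonization_report <- function(x, ...) {
  tab <- table(factor(x$outcomes$outcome,
                      levels = c("primary", "secondary_mapped",
                                 "obsolete_dropped", "taxon_dropped",
                                 "unknown_dropped")))
  cat("harmonization_report:", nrow(x$outcomes), "distinct inputs |",
      paste(names(tab), tab, sep = "=", collapse = " "), "|",
      x$isoforms_stripped, "isoform id(s) stripped\n")
  invisible(x)
}

#' Tabulate a harmonization report's outcome buckets
#'
#' @param report a `harmonization_report`.
#' @return data.frame with columns `outcome`, `n`, `fraction` (of distinct
#'   inputs after isoform stripping).
#' @export
harmonization_fractions <- function(report) {
  lv <- c("primary", "secondary_mapped", "obsolete_dropped", "taxon_dropped",
          "unknown_dropped")
  n <- as.integer(table(factor(report$outcomes$outcome, levels = lv)))
  total <- nrow(report$outcomes)
  data.frame(outcome = lv, n = n,
             fraction = if (total) n / total else rep(0, length(lv)),
             stringsAsFactors = FALSE)
}
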