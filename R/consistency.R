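#' Phosphorylatable residue set
#'
#' The audit limits phosphorylatable residues to serine, threonine and
#' tyrosine by default; the set is configurable (e.g. to add histidine) but
#' must be non-empty and uppercase.
#'
#' @param residues character vector of single uppercase letters.
#' @return a validated character vector.
#' @export
phospho_residues <- function(residues = c("S", "T", "Y")) {
  residues <- toupper(as.character(residues))
  if (!length(residues) || any(nchar(residues) != 1L)) {
    stop("phospho residue set must be non-empty single letters")
  }
  unique(residues)
}

#' Residue at a 1-based position
#'
#' @param sequence amino-acid string.
#' @param position integer position, 1-based; must be >= 1.
#' @return the letter at `position`, or `NA_character_` when the position
#'   exceeds the sequence length.
#' @export
residue_at <- function(sequence, position) {
  position <- as.integer(position)
  if (is.na(position) || position < 1L) stop("position must be >= 1")
  if (position > nchar(sequence)) return(NA_character_)
  substr(sequence, position, position)
}

#' Closest exact occurrence of a residue
#'
#' Searches `sequence` for the occurrence of `residue` nearest to the
#' annotated position and records the signed offset, defined as annotated
#' position minus matched position. When two occurrences are equidistant the
#' negative signed offset wins (the later occurrence), because initiator-Met
#' cleavage — the dominant known cause of systematic coordinate shifts —
#' produces offsets of -1.
#'
#' @param sequence amino-acid string.
#' @param residue single letter to search for.
#' @param position annotated 1-based position (need not lie within the
#'   sequence).
#' @return a list with `matched_position` and `signed_offset`, or `NULL`
#'   when the residue does not occur in the sequence.
#' @export
nearest_occurrence <- function(sequence, residue, position) {
  position <- as.integer(position)
  if (is.na(position) || position < 1L) stop("position must be >= 1")
  occ <- which(strsplit(sequence, "", fixed = TRUE)[[1]] == residue)
  if (!length(occ)) return(NULL)
  d <- abs(occ - position)
  cand <- occ[d == min(d)]
  matched <- max(cand)  # tie: prefer the later occurrence (negative offset)
  list(matched_position = matched,
       signed_offset = position - matched)
}

offset_bin <- function(signed_offset) {
  m <- abs(signed_offset)
  if (m >= 4L) "+" else as.character(m)
}

#' Classify one phosphosite annotation against its sequence record
#'
#' Categories, in precedence order: (1) canonical match — the annotated
#' residue sits at the annotated position of the canonical sequence;
#' (2) isoform match — it sits at that position in an isoform (first isoform
#' in catalog order wins); (3) mismatch — a different phosphorylatable
#' residue occupies the canonical position; (4) offset — the nearest exact
#' occurrence on the canonical sequence, with the signed offset (annotated
#' minus matched) recorded and binned by magnitude into 1 / 2 / 3 / "+";
#' (5) isoform mismatch, then isoform offset, searched only when the
#' annotated residue is absent from the canonical sequence entirely;
#' (6) unmatched. A position beyond the canonical length triggers no
#' mismatch or offset search on the canonical: it is an isoform match or
#' unmatched.
#'
#' @param site one-row site data.frame or list with `accession`, `residue`,
#'   `position`.
#' @param record the `sequence_record` for `site$accession`.
#' @param residues phosphorylatable residue set (see [phospho_residues()]).
#' @return a one-row data.frame with columns `accession`, `residue`,
#'   `position`, `category`, `matched_in` (`"canonical"`, an isoform id, or
#'   `NA`), `matched_position`, `signed_offset`, `magnitude_bin`.
#' @export
classify_site <- function(site, record, residues = phospho_residues()) {
  if (!identical(as.character(site$accession), record$accession)) {
    stop("record ", record$accession, " does not belong to site accession ",
         site$accession)
  }
  res <- toupper(as.character(site$residue))
  pos <- as.integer(site$position)
  canon <- record$canonical

  cls <- function(category, matched_in = NA_character_,
                  matched_position = NA_integer_,
                  signed_offset = NA_integer_) {
    data.frame(accession = record$accession, residue = res, position = pos,
               category = category, matched_in = matched_in,
               matched_position = as.integer(matched_position),
               signed_offset = as.integer(signed_offset),
               magnitude_bin = if (is.na(signed_offset) ||
                                   category != "offset") NA_character_
                               else offset_bin(signed_offset),
               stringsAsFactors = FALSE)
  }

  # (1) canonical match
  if (pos <= nchar(canon) && residue_at(canon, pos) == res) {
    return(cls("canonical_match", "canonical", pos, 0L))
  }
  # (2) isoform match, first isoform in catalog order
  for (iso_id in names(record$isoforms)) {
    iso <- record$isoforms[[iso_id]]
    if (pos <= nchar(iso) && residue_at(iso, pos) == res) {
      return(cls("isoform_match", iso_id, pos, 0L))
    }
  }
  # beyond the canonical length: no canonical mismatch/offset search
  if (pos > nchar(canon)) {
    return(cls("unmatched"))
  }
  # (3) canonical mismatch: another phosphorylatable residue occupies pos
  occupant <- residue_at(canon, pos)
  if (occupant %in% residues) {
    return(cls("mismatch", "canonical"))
  }
  # (4) canonical offset: closest exact occurrence
  hit <- nearest_occurrence(canon, res, pos)
  if (!is.null(hit)) {
    return(cls("offset", "canonical", hit$matched_position, hit$signed_offset))
  }
  # (5) residue wholly absent from the canonical: search isoforms
  for (iso_id in names(record$isoforms)) {
    iso <- record$isoforms[[iso_id]]
    if (pos <= nchar(iso) && residue_at(iso, pos) %in% residues) {
      return(cls("mismatch", iso_id))
    }
  }
  for (iso_id in names(record$isoforms)) {
    hit <- nearest_occurrence(record$isoforms[[iso_id]], res, pos)
    if (!is.null(hit)) {
      return(cls("offset", iso_id, hit$matched_position, hit$signed_offset))
    }
  }
  # (6) nothing matched anywhere
  cls("unmatched")
}

#' Classify every site of an annotation set
#'
#' @param set an `annotation_set` whose accessions are primary catalog
#'   records (i.e. already harmonized).
#' @param catalog a `sequence_catalog`.
#' @param residues phosphorylatable residue set.
#' @return a data.frame with one classification row per site (columns as in
#'   [classify_site()]).
#' @export
classify_sites <- function(set, catalog, residues = phospho_residues()) {
  sites <- set$sites
  unknown <- setdiff(unique(sites$accession), names(catalog$records))
  if (length(unknown)) {
    stop("sites reference accessions absent from the catalog: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (!nrow(sites)) {
    return(classify_site(list(accession = "x", residue = "S", position = 1L),
                         sequence_record("x", "S"))[0, ])
  }
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    classify_site(sites[i, ], catalog$records[[sites$accession[i]]], residues)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tally classifications into a consistency summary
#'
#' The summary mirrors the audit's per-database table: total modified
#' residues, canonical matches and their percentage (isoform matches are
#' excluded from the numerator but counted in the denominator), isoform
#' matches, mismatches, the closest-exact-match offset histogram binned by
#' magnitude 1 / 2 / 3 / "+" (>= 4), and unmatched sites. The five
#' categories partition the input.
#'
#' @param classifications data.frame from [classify_sites()].
#' @return an object of class `consistency_summary`.
#' @export
summarize_consistency <- function(classifications) {
  cat_tab <- table(factor(classifications$category,
                          levels = c("canonical_match", "isoform_match",
                                     "mismatch", "offset", "unmatched")))
  n <- nrow(classifications)
  off <- classifications$signed_offset[classifications$category == "offset"]
  hist <- table(factor(vapply(off, offset_bin, character(1)),
                       levels = c("1", "2", "3", "+")))
  out <- structure(list(
    n_sites = n,
    n_consistent = as.integer(cat_tab[["canonical_match"]]),
    pct_consistent = if (n) unname(cat_tab[["canonical_match"]]) / n else 0,
    n_isoform = as.integer(cat_tab[["isoform_match"]]),
    n_mismatch = as.integer(cat_tab[["mismatch"]]),
    offset_histogram = stats::setNames(as.integer(hist), names(hist)),
    n_unmatched = as.integer(cat_tab[["unmatched"]])),
    class = "consistency_summary")
  stopifnot(out$n_consistent + out$n_isoform + out$n_mismatch +
              sum(out$offset_histogram) + out$n_unmatched == out$n_sites)
  out
}

#' @export
print.consistency_summary <- function(x, ...) {
  cat("consistency_summary:", x$n_sites, "sites;",
      sprintf("%.1f%%", 100 * x$pct_consistent), "consistent;",
      x$n_isoform, "isoform matches;", x$n_mismatch, "mismatches;",
      "offsets", paste(names(x$offset_histogram), x$offset_histogram,
                       sep = "=", collapse = " "), ";",
      x$n_unmatched, "unmatched\n")
  invisible(x)
}

#' Render a consistency summary as a one-row table
#'
#' @param summary a `consistency_summary`.
#' @param name resource name for the `database` column.
#' @return a one-row data.frame in the per-database audit layout.
#' @export
consistency_summary_row <- function(summary, name) {
  data.frame(database = name, n_sites = summary$n_sites,
             n_consistent = summary$n_consistent,
             pct_consistent = round(100 * summary$pct_consistent, 1),
             isoform_matches = summary$n_isoform,
             mismatches = summary$n_mismatch,
             offset_1 = summary$offset_histogram[["1"]],
             offset_2 = summary$offset_histogram[["2"]],
             offset_3 = summary$offset_histogram[["3"]],
             offset_4plus = summary$offset_histogram[["+"]],
             unmatched = summary$n_unmatched, stringsAsFactors = FALSE)
}
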