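#' Annotation sets
#'
#' One resource's extracted content after (or before) harmonization: a named
#' set of protein base accessions and a set of phosphosites. Sites are
#' deduplicated on the (accession, residue, position) triple and both
#' components are stored sorted, so sets built from permuted input compare
#' equal.
#'
#' @param name resource name.
#' @param proteins character vector of base accessions.
#' @param sites a site data.frame (see [site_table()]).
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(name, proteins = character(), sites = site_table()) {
  structure(list(name = as.character(name),
                 proteins = sort(unique(as.character(proteins))),
                 sites = normalize_sites(sites)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set '", x$name, "': ", length(x$proteins), " proteins, ",
      nrow(x$sites), " sites\n", sep = "")
  invisible(x)
}

#' Read one resource's annotation TSV
#'
#' Expects a UTF-8 tab-delimited file with a header row and columns
#' `accession`, `residue`, `position`. Rows with empty residue and position
#' contribute only to the protein set; rows with a site contribute the
#' accession to the protein set as well. Duplicate triples are collapsed and
#' row order never changes the result. Malformed rows (non-integer position,
#' residue longer than one letter, missing accession) are collected into a
#' rejects report attached as the `"rejects"` attribute, not raised as
#' errors.
#'
#' @param tsv_path path to the TSV file.
#' @param name resource name to record on the set.
#' @return an `annotation_set`; `attr(, "rejects")` is a data.frame with
#'   columns `line`, `field`, `reason` (line numbers count the header as
#'   line 1).
#' @export
read_annotation_set <- function(tsv_path, name) {
  tab <- utils::read.delim(tsv_path, colClasses = "character",
                           stringsAsFactors = FALSE, na.strings = NULL)
  needed <- c("accession", "residue", "position")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  }
  rejects <- empty_rejects()
  proteins <- character()
  acc <- trimws(tab$accession)
  res <- trimws(tab$residue)
  pos_raw <- trimws(tab$position)

  keep_site <- logical(nrow(tab))
  pos <- rep(NA_integer_, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    line <- i + 1L  # header is line 1
    if (!nzchar(acc[i])) {
      rejects <- add_reject(rejects, line, "accession", "missing accession")
      next
    }
    if (!nzchar(res[i]) && !nzchar(pos_raw[i])) {
      proteins <- c(proteins, acc[i])
      next
    }
    if (nchar(res[i]) != 1L) {
      rejects <- add_reject(rejects, line, "residue",
                            paste0("residue not a single letter: '", res[i], "'"))
      next
    }
    p <- suppressWarnings(as.integer(pos_raw[i]))
    if (is.na(p) || p < 1L || as.character(p) != sub("^\\+", "", pos_raw[i])) {
      rejects <- add_reject(rejects, line, "position",
                            paste0("position not a positive integer: '",
                                   pos_raw[i], "'"))
      next
    }
    keep_site[i] <- TRUE
    pos[i] <- p
    proteins <- c(proteins, acc[i])
  }
  sites <- site_table(acc[keep_site], res[keep_site], pos[keep_site])
  out <- annotation_set(name, proteins = proteins, sites = sites)
  attr(out, "rejects") <- rejects
  out
}

empty_rejects <- function() {
  data.frame(line = integer(), field = character(), reason = character(),
             stringsAsFactors = FALSE)
}

add_reject <- function(rejects, line, field, reason) {
  rbind(rejects, data.frame(line = as.integer(line), field = field,
                            reason = reason, stringsAsFactors = FALSE))
}

#' Write an annotation set as a TSV readable by [read_annotation_set()]
#'
#' Site rows are written first (sorted), followed by protein-only rows for
#' proteins that carry no site, so the round trip reproduces the set.
#'
#' @param set an `annotation_set`.
#' @param tsv_path output path.
#' @return the path, invisibly.
#' @export
write_annotation_set <- function(set, tsv_path) {
  site_rows <- set$sites
  site_rows$position <- as.character(site_rows$position)
  bare <- setdiff(set$proteins, unique(set$sites$accession))
  if (length(bare)) {
    site_rows <- rbind(site_rows,
                       data.frame(accession = sort(bare), residue = "",
                                  position = "", stringsAsFactors = FALSE))
  }
  utils::write.table(site_rows, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tsv_path)
}
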