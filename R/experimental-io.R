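#' Experimental phosphosite records
#'
#' qPhos-style experimental tables list one row per (site, PMID, sample)
#' pairing. Because a publication's sites cannot be attributed to one of
#' several conditions after the fact, sample labels are merged per PMID:
#' every record carrying a PMID carries that PMID's full sample-label set.
#' The container keeps a deduplicated `(accession, residue, position, pmid)`
#' record table plus the PMID-to-samples map.
#'
#' @param records data.frame with columns `accession`, `residue`,
#'   `position`, `pmid`.
#' @param pmid_samples named list mapping each PMID to a non-empty character
#'   vector of sample labels.
#' @return an object of class `experimental_records`.
#' @export
experimental_records <- function(records, pmid_samples) {
  records <- unique(data.frame(accession = as.character(records$accession),
                               residue = toupper(as.character(records$residue)),
                               position = as.integer(records$position),
                               pmid = as.character(records$pmid),
                               stringsAsFactors = FALSE))
  o <- order(records$pmid, records$accession, records$position, records$residue)
  records <- records[o, , drop = FALSE]
  rownames(records) <- NULL
  pmid_samples <- lapply(pmid_samples, function(s) sort(unique(as.character(s))))
  pmid_samples <- pmid_samples[order(names(pmid_samples))]
  if (any(!lengths(pmid_samples))) stop("every PMID needs at least one sample")
  missing <- setdiff(unique(records$pmid), names(pmid_samples))
  if (length(missing)) {
    stop("records carry PMIDs without sample labels: ",
         paste(missing, collapse = ", "))
  }
  structure(list(records = records, pmid_samples = pmid_samples),
            class = "experimental_records")
}

#' @export
print.experimental_records <- function(x, ...) {
  cat("experimental_records:", nrow(x$records), "site-PMID records,",
      length(x$pmid_samples), "PMIDs,",
      length(unique(unlist(x$pmid_samples))), "samples\n")
  invisible(x)
}

#' Read an experimental table
#'
#' Expects TSV columns `accession`, `residue`, `position`, `pmid`, `sample`,
#' one row per (site, pmid, sample). Rows sharing a PMID have their sample
#' labels merged into that PMID's sample set on every record carrying it.
#' Rows missing a PMID, accession or a valid position are rejected with a
#' logged reason (`attr(, "rejects")`).
#'
#' @param tsv_path path to the TSV.
#' @return an `experimental_records` object with a `"rejects"` attribute.
#' @export
read_experimental <- function(tsv_path) {
  tab <- utils::read.delim(tsv_path, colClasses = "character",
                           stringsAsFactors = FALSE, na.strings = NULL)
  needed <- c("accession", "residue", "position", "pmid", "sample")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("experimental table lacks column(s): ", paste(missing, collapse = ", "))
  }
  rejects <- empty_rejects()
  ok <- logical(nrow(tab))
  pos <- rep(NA_integer_, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    line <- i + 1L
    if (!nzchar(trimws(tab$pmid[i]))) {
      rejects <- add_reject(rejects, line, "pmid", "missing pmid")
      next
    }
    if (!nzchar(trimws(tab$accession[i]))) {
      rejects <- add_reject(rejects, line, "accession", "missing accession")
      next
    }
    p <- suppressWarnings(as.integer(trimws(tab$position[i])))
    if (is.na(p) || p < 1L) {
      rejects <- add_reject(rejects, line, "position",
                            paste0("position not a positive integer: '",
                                   tab$position[i], "'"))
      next
    }
    if (nchar(trimws(tab$residue[i])) != 1L) {
      rejects <- add_reject(rejects, line, "residue",
                            paste0("residue not a single letter: '",
                                   tab$residue[i], "'"))
      next
    }
    if (!nzchar(trimws(tab$sample[i]))) {
      rejects <- add_reject(rejects, line, "sample", "missing sample label")
      next
    }
    ok[i] <- TRUE
    pos[i] <- p
  }
  kept <- tab[ok, , drop = FALSE]
  kept$position <- pos[ok]
  pmid_samples <- lapply(split(trimws(kept$sample), kept$pmid),
                         function(s) sort(unique(s[nzchar(s)])))
  out <- experimental_records(kept[, c("accession", "residue", "position",
                                       "pmid")],
                              pmid_samples)
  attr(out, "rejects") <- rejects
  out
}

#' Write experimental records as a TSV readable by [read_experimental()]
#'
#' Each record row is expanded to one row per sample label of its PMID, so
#' the round trip reproduces the record list and the PMID sample sets.
#'
#' @param records an `experimental_records` object.
#' @param tsv_path output path.
#' @return the path, invisibly.
#' @export
write_experimental <- function(records, tsv_path) {
  df <- records$records
  rows <- lapply(seq_len(nrow(df)), function(i) {
    samples <- records$pmid_samples[[df$pmid[i]]]
    data.frame(accession = df$accession[i], residue = df$residue[i],
               position = as.character(df$position[i]), pmid = df$pmid[i],
               sample = samples, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(), residue = character(),
               position = character(), pmid = character(),
               sample = character(), stringsAsFactors = FALSE)
  utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tsv_path)
}
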