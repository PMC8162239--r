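#' Phosphosite tables
#'
#' A phosphosite is the triple (base accession, residue letter, 1-based
#' position). Site identity across resources is exact triple equality; no
#' sequence-window standardization is attempted. Site tables are plain
#' data.frames with columns `accession`, `residue`, `position`, kept
#' deduplicated and sorted so that equal site sets compare equal regardless
#' of input order.
#'
#' @param accession character vector of base accessions.
#' @param residue single uppercase residue letters.
#' @param position integer positions, 1-based.
#' @return a normalized site data.frame.
#' @export
site_table <- function(accession = character(), residue = character(),
                       position = integer()) {
  df <- data.frame(accession = as.character(accession),
                   residue = toupper(as.character(residue)),
                   position = as.integer(position),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(is.na(df$position)) || any(df$position < 1L)) {
      stop("site positions must be integers >= 1")
    }
    if (any(nchar(df$residue) != 1L)) {
      stop("residue must be a single letter")
    }
  }
  normalize_sites(df)
}

# dedupe on the triple and impose a deterministic row order
normalize_sites <- function(df) {
  df <- unique(df[, c("accession", "residue", "position")])
  o <- order(df$accession, df$position, df$residue)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Render sites as unique string keys
#'
#' @param sites a site data.frame (see [site_table()]).
#' @return character keys `"accession|residue|position"`, one per row.
#' @export
site_key <- function(sites) {
  if (!nrow(sites)) return(character())
  paste(sites$accession, sites$residue, sites$position, sep = "|")
}

empty_sites <- function() site_table()
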