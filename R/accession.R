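#' Parse protein accessions with optional isoform suffix
#'
#' Accessions follow the UniProt shape: a base token (a letter followed by
#' 5 or 9 alphanumerics by default) optionally extended with `-<k>` to name
#' isoform `k` (k >= 1). Parsing the rendered form recovers both fields.
#'
#' @param x character vector of accession strings.
#' @param base_pattern regular expression a bare base must match. The default
#'   accepts the 6- and 10-character UniProt formats; synthetic catalogs may
#'   relax it.
#' @return a data.frame with columns `base` (character) and `isoform_index`
#'   (integer, `NA` when the accession is not an isoform).
#' @examples
#' parse_accession(c("P04637", "P04637-2"))
#' @export
parse_accession <- function(x, base_pattern = uniprot_base_pattern()) {
  x <- as.character(x)
  has_iso <- grepl("-[0-9]+$", x)
  base <- sub("-[0-9]+$", "", x)
  iso <- rep(NA_integer_, length(x))
  iso[has_iso] <- as.integer(sub("^-", "", regmatches(x, regexpr("-[0-9]+$", x))))
  bad <- !grepl(base_pattern, base)
  if (any(bad)) {
    stop("invalid accession(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  if (any(!is.na(iso) & iso < 1L)) {
    stop("isoform index must be >= 1")
  }
  data.frame(base = base, isoform_index = iso, stringsAsFactors = FALSE)
}

#' @rdname parse_accession
#' @param base base accession(s).
#' @param isoform_index integer isoform index or `NA` for the canonical entry.
#' @export
render_accession <- function(base, isoform_index = NA_integer_) {
  out <- ifelse(is.na(isoform_index), base,
                paste0(base, "-", as.integer(isoform_index)))
  as.character(out)
}

#' Default pattern for a UniProt-style base accession
#' @return a regular expression string.
#' @export
uniprot_base_pattern <- function() {
  "^[A-Za-z][A-Za-z0-9]{5}([A-Za-z0-9]{4})?$"
}

#' Strip the isoform suffix from accessions
#'
#' Annotated isoforms are removed before comparison across resources so that
#' all databases are compared at the gene-product (base accession) level:
#' `"P04637-2"` becomes `"P04637"`, bare bases pass through unchanged.
#'
#' @param acc character vector of accessions, possibly isoform-suffixed.
#' @return character vector of base accessions.
#' @export
strip_isoform <- function(acc) {
  sub("-[0-9]+$", "", as.character(acc))
}
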