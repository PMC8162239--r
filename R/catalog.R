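#' Sequence records and catalogs
#'
#' A `sequence_record` holds one protein: its base accession, review status
#' (Swiss-Prot-style reviewed vs automatically annotated), NCBI taxon, the
#' canonical amino-acid sequence and an ordered set of isoform sequences.
#' A `sequence_catalog` is the reference proteome stand-in: primary records
#' keyed by base accession plus the identifier bookkeeping needed for
#' harmonization (secondary-to-primary map, obsolete set, reference taxon).
#'
#' @param accession base accession.
#' @param canonical uppercase amino-acid string (20-letter alphabet plus X).
#' @param reviewed logical; `TRUE` for reviewed (sp) entries.
#' @param taxon integer NCBI taxon id.
#' @param isoforms named character vector of isoform sequences; names are the
#'   full isoform accessions (e.g. `"P00001-2"`) and must be distinct.
#' @return an object of class `sequence_record`.
#' @export
sequence_record <- function(accession, canonical, reviewed = TRUE,
                            taxon = 9606L, isoforms = character()) {
  canonical <- toupper(canonical)
  if (!nzchar(canonical)) stop("canonical sequence must be non-empty: ", accession)
  check_aa(canonical, accession)
  if (length(isoforms)) {
    isoforms <- toupper(isoforms)
    if (is.null(names(isoforms)) || anyDuplicated(names(isoforms)) ||
        any(names(isoforms) == accession)) {
      stop("isoform ids must be distinct and differ from the canonical id: ",
           accession)
    }
    for (i in seq_along(isoforms)) check_aa(isoforms[[i]], names(isoforms)[i])
  }
  structure(list(accession = as.character(accession),
                 reviewed = isTRUE(reviewed),
                 taxon = as.integer(taxon),
                 canonical = canonical,
                 isoforms = isoforms),
            class = "sequence_record")
}

check_aa <- function(seq, label) {
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seq)) {
    stop("sequence of ", label, " contains letters outside the amino-acid alphabet")
  }
  invisible(TRUE)
}

#' @rdname sequence_record
#' @param records list of `sequence_record` objects.
#' @param secondary_to_primary named character vector mapping secondary base
#'   accessions to primary bases present in `records`.
#' @param obsolete character vector of retired base accessions.
#' @param reference_taxon taxon id of the reference organism (human, 9606).
#' @export
sequence_catalog <- function(records = list(),
                             secondary_to_primary = character(),
                             obsolete = character(),
                             reference_taxon = 9606L) {
  if (length(records)) {
    names(records) <- vapply(records, function(r) r$accession, character(1))
  }
  cat <- structure(list(records = records,
                        secondary_to_primary = secondary_to_primary,
                        obsolete = as.character(obsolete),
                        reference_taxon = as.integer(reference_taxon)),
                   class = "sequence_catalog")
  validate_catalog(cat)
  cat
}

#' Validate the internal consistency of a sequence catalog
#'
#' Checks that secondary and obsolete accession sets are disjoint from the
#' primary records and that every secondary accession maps to a known
#' primary.
#'
#' @param catalog a `sequence_catalog`.
#' @return the catalog, invisibly; stops on violation.
#' @export
validate_catalog <- function(catalog) {
  prim <- names(catalog$records)
  sec <- names(catalog$secondary_to_primary)
  if (length(intersect(sec, prim))) {
    stop("secondary accessions overlap primary records: ",
         paste(intersect(sec, prim), collapse = ", "))
  }
  if (length(intersect(catalog$obsolete, prim))) {
    stop("obsolete accessions overlap primary records: ",
         paste(intersect(catalog$obsolete, prim), collapse = ", "))
  }
  unknown <- setdiff(unname(catalog$secondary_to_primary), prim)
  if (length(unknown)) {
    stop("secondary accession maps to unknown primary: ",
         paste(unknown, collapse = ", "))
  }
  invisible(catalog)
}

#' @export
print.sequence_catalog <- function(x, ...) {
  cat("sequence_catalog:", length(x$records), "primary records,",
      length(x$secondary_to_primary), "secondary,",
      length(x$obsolete), "obsolete; reference taxon", x$reference_taxon, "\n")
  invisible(x)
}

#' Read a reference catalog from FASTA and an identifier-status table
#'
#' The FASTA must use the pipe-delimited UniProt header dialect
#' `>sp|ACC|NAME` / `>tr|ACC|NAME`, with isoforms as `>sp|ACC-2|NAME`.
#' Isoform entries are attached to their base record and never emitted as
#' standalone records; `reviewed` is true exactly for `sp` entries. The id
#' table is a TSV with columns `accession`, `status` (primary / secondary /
#' obsolete), `maps_to` and `taxon`; it supplies per-record taxa and the
#' secondary/obsolete bookkeeping.
#'
#' @param fasta_path path to the FASTA file.
#' @param id_table_path path to the id-status TSV.
#' @param reference_taxon reference organism taxon id (default human, 9606).
#' @return a `sequence_catalog`.
#' @export
read_catalog <- function(fasta_path, id_table_path, reference_taxon = 9606L) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  headers <- names(seqs)
  header_lines <- grep("^>", readLines(fasta_path))

  parts <- strsplit(headers, "|", fixed = TRUE)
  ok <- lengths(parts) == 3L &
    vapply(parts, function(p) p[1] %in% c("sp", "tr"), logical(1))
  if (any(!ok)) {
    i <- which(!ok)[1]
    stop("malformed FASTA header at line ", header_lines[i], ": >", headers[i])
  }

  acc_full <- vapply(parts, `[`, character(1), 2L)
  db_tag <- vapply(parts, `[`, character(1), 1L)
  acc <- parse_accession(acc_full)
  is_iso <- !is.na(acc$isoform_index)

  id_tab <- read_id_table(id_table_path)
  taxon_of <- function(base) {
    hit <- id_tab$taxon[id_tab$accession == base & id_tab$status == "primary"]
    if (length(hit) && !is.na(hit[1])) hit[1] else as.integer(reference_taxon)
  }

  records <- list()
  for (i in which(!is_iso)) {
    base <- acc$base[i]
    if (!is.null(records[[base]])) {
      stop("duplicate canonical entry for ", base, " at line ", header_lines[i])
    }
    records[[base]] <- sequence_record(
      accession = base,
      canonical = as.character(seqs[[i]]),
      reviewed = db_tag[i] == "sp",
      taxon = taxon_of(base))
  }
  for (i in which(is_iso)) {
    base <- acc$base[i]
    if (is.null(records[[base]])) {
      stop("isoform entry without canonical record: ", acc_full[i],
           " at line ", header_lines[i])
    }
    iso <- records[[base]]$isoforms
    iso[[acc_full[i]]] <- toupper(as.character(seqs[[i]]))
    records[[base]]$isoforms <- iso
  }

  sec_rows <- id_tab[id_tab$status == "secondary", , drop = FALSE]
  secondary <- structure(sec_rows$maps_to, names = sec_rows$accession)
  obsolete <- id_tab$accession[id_tab$status == "obsolete"]
  sequence_catalog(records, secondary_to_primary = secondary,
                   obsolete = obsolete,
                   reference_taxon = reference_taxon)
}

read_id_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE)
  needed <- c("accession", "status", "maps_to", "taxon")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("id table lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- !tab$status %in% c("primary", "secondary", "obsolete")
  if (any(bad)) {
    stop("id table has unknown status at data row ", which(bad)[1], ": ",
         tab$status[which(bad)[1]])
  }
  tab$taxon <- suppressWarnings(as.integer(tab$taxon))
  tab
}

#' Write a catalog back to FASTA plus an id-status table
#'
#' Inverse of [read_catalog()]: emits one canonical entry per record
#' (`sp`/`tr` by review status) followed by its isoforms, and an id table
#' carrying primary taxa, secondary mappings and obsolete accessions.
#' `read_catalog()` on the output reproduces the catalog exactly.
#'
#' @param catalog a `sequence_catalog`.
#' @param fasta_path,id_table_path output paths.
#' @return invisibly, the two paths.
#' @export
write_catalog <- function(catalog, fasta_path, id_table_path) {
  seqs <- character()
  for (r in catalog$records) {
    tag <- if (r$reviewed) "sp" else "tr"
    seqs[paste(tag, r$accession, r$accession, sep = "|")] <- r$canonical
    for (iso_id in names(r$isoforms)) {
      seqs[paste(tag, iso_id, r$accession, sep = "|")] <- r$isoforms[[iso_id]]
    }
  }
  aset <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aset, fasta_path)

  prim <- data.frame(accession = names(catalog$records),
                     status = "primary", maps_to = "",
                     taxon = vapply(catalog$records, function(r) r$taxon,
                                    integer(1)),
                     stringsAsFactors = FALSE)
  sec <- data.frame(accession = names(catalog$secondary_to_primary),
                    status = rep("secondary",
                                 length(catalog$secondary_to_primary)),
                    maps_to = unname(catalog$secondary_to_primary),
                    taxon = NA_integer_, stringsAsFactors = FALSE)
  obs <- data.frame(accession = catalog$obsolete,
                    status = rep("obsolete", length(catalog$obsolete)),
                    maps_to = "", taxon = NA_integer_,
                    stringsAsFactors = FALSE)
  tab <- rbind(prim, sec, obs)
  utils::write.table(tab, id_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(fasta = fasta_path, id_table = id_table_path))
}
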