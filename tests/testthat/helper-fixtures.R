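# Small in-code fixtures and independent oracles used across the suite.

tiny_catalog <- function() {
  sequence_catalog(
    records = list(
      sequence_record("P00001", "MSTYAAAKLT", reviewed = TRUE, taxon = 9606L,
                      isoforms = c("P00001-2" = "MSYAAAKL")),
      sequence_record("P00002", "MKKKSSSTTT", reviewed = TRUE, taxon = 9606L),
      sequence_record("P00003", "MAAAAAAAAA", reviewed = FALSE, taxon = 9606L),
      sequence_record("P00004", "MSTYKLMNPQ", reviewed = TRUE, taxon = 10090L)),
    secondary_to_primary = c("P00009" = "P00001", "P00008" = "P00004"),
    obsolete = "P00007",
    reference_taxon = 9606L)
}

random_aa_seq <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), len, replace = TRUE),
        collapse = "")
}

# exhaustive linear-scan oracle for the closest exact occurrence; ties prefer
# the later occurrence (negative signed offset), scanned position by position
oracle_nearest <- function(sequence, residue, position) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  best <- NULL
  for (i in seq_along(chars)) {
    if (chars[i] != residue) next
    if (is.null(best) ||
        abs(i - position) < abs(best - position) ||
        (abs(i - position) == abs(best - position) && i > best)) {
      best <- i
    }
  }
  if (is.null(best)) return(NULL)
  list(matched_position = best, signed_offset = position - best)
}

# per-element membership-signature enumeration oracle for UpSet counts
oracle_exclusive <- function(sets) {
  nm <- names(sets)
  counts <- new.env()
  for (el in unique(unlist(sets, use.names = FALSE))) {
    sig <- paste(nm[vapply(sets, function(s) el %in% s, logical(1))],
                 collapse = "&")
    counts[[sig]] <- (counts[[sig]] %||0% 0L) + 1L
  }
  out <- data.frame(signature = ls(counts),
                    count = vapply(ls(counts), function(s) counts[[s]],
                                   integer(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

`%||0%` <- function(x, y) if (is.null(x)) y else x

# factorial-based hypergeometric upper tail, independent of phyper
oracle_hyper_upper <- function(k, K, N, n) {
  point <- function(i) {
    choose_f(K, i) * choose_f(N - K, n - i) / choose_f(N, n)
  }
  sum(vapply(k:min(K, n), point, numeric(1)))
}

choose_f <- function(a, b) {
  if (b < 0 || b > a) return(0)
  factorial(a) / (factorial(b) * factorial(a - b))
}

# brute-force enumeration of the one-to-one identifier selection rule
oracle_resolve <- function(candidates, catalog) {
  if (!length(candidates)) return(NA_character_)
  info <- lapply(candidates, function(a) catalog$records[[a]])
  reviewed <- vapply(info, function(r) r$reviewed, logical(1))
  pool <- if (any(reviewed)) candidates[reviewed] else candidates
  best <- NULL
  for (a in sort(pool)) {
    len <- nchar(catalog$records[[a]]$canonical)
    if (is.null(best) || len > nchar(catalog$records[[best]]$canonical)) {
      best <- a
    }
  }
  best
}

write_tiny_fasta <- function(path, entries) {
  # entries: named character vector, names are full ">"-less headers
  lines <- character()
  for (h in names(entries)) lines <- c(lines, paste0(">", h), entries[[h]])
  writeLines(lines, path)
  path
}

write_id_table <- function(path, df = NULL) {
  if (is.null(df)) {
    df <- data.frame(accession = character(), status = character(),
                     maps_to = character(), taxon = character())
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
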