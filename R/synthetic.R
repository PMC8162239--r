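AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specification for a synthetic audit study
#'
#' Bundles every knob of the synthetic-data generator with the planted
#' ground truth the pipeline must recover. Defaults describe the standing
#' study conditions: a 1,000-protein human catalog with 200-600-residue
#' sequences and up to two isoforms per record; 10% secondary, 5% obsolete
#' and 5% foreign-taxon identifiers; 100 planted site annotations split
#' 60/10/5/20/5 across canonical match / isoform match / mismatch / offset /
#' unmatched, with offset magnitudes dominated by -1 (initiator-Met
#' cleavage); five databases with a fixed exclusive-intersection vector; and
#' six cell-line labels with 20% of publications tagged multi-sample.
#'
#' @param seed integer seed; mandatory, drives every random draw.
#' @param n_proteins number of human primary records.
#' @param length_range integer range of canonical sequence lengths.
#' @param isoform_count_range integer range of isoforms per record.
#' @param fraction_secondary,fraction_obsolete,fraction_foreign_taxon
#'   fractions of `n_proteins` generating secondary, obsolete and
#'   foreign-taxon identifiers.
#' @param category_counts list with integer counts `canonical_match`,
#'   `isoform_match`, `mismatch`, `unmatched` and an integer vector
#'   `offsets` of signed offsets (one planted site per entry).
#' @param membership_names database names for the membership structure.
#' @param membership_vector named integer vector of exclusive-intersection
#'   counts; names are `&`-joined subsets of `membership_names`.
#' @param samples list with `labels`, `pmids_per_sample` (recycled),
#'   `sites_per_pmid` and `multi_sample_fraction`.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed,
                           n_proteins = 1000L,
                           length_range = c(200L, 600L),
                           isoform_count_range = c(0L, 2L),
                           fraction_secondary = 0.10,
                           fraction_obsolete = 0.05,
                           fraction_foreign_taxon = 0.05,
                           category_counts = list(
                             canonical_match = 60L,
                             isoform_match = 10L,
                             mismatch = 5L,
                             offsets = c(rep(-1L, 8L), 1L, 1L, 2L, 2L, -2L,
                                         3L, 3L, -3L, 4L, 5L, 7L, -10L),
                             unmatched = 5L),
                           membership_names = paste0("db", 1:5),
                           membership_vector = c(
                             "db1" = 30L, "db2" = 20L, "db3" = 15L,
                             "db4" = 10L, "db5" = 5L,
                             "db1&db2" = 8L, "db2&db3" = 6L,
                             "db1&db2&db3" = 4L,
                             "db1&db2&db3&db4&db5" = 2L),
                           samples = list(
                             labels = c("HeLa", "HEK293", "HeLa S3",
                                        "Jurkat", "MCF-7", "MCF-10A"),
                             pmids_per_sample = c(30L, 25L, 20L, 15L, 12L, 8L),
                             sites_per_pmid = 20L,
                             multi_sample_fraction = 0.2)) {
  if (missing(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    stop("a seed is mandatory")
  }
  spec <- structure(list(seed = as.integer(seed),
                         n_proteins = as.integer(n_proteins),
                         length_range = as.integer(length_range),
                         isoform_count_range = as.integer(isoform_count_range),
                         fraction_secondary = fraction_secondary,
                         fraction_obsolete = fraction_obsolete,
                         fraction_foreign_taxon = fraction_foreign_taxon,
                         category_counts = category_counts,
                         membership_names = membership_names,
                         membership_vector = membership_vector,
                         samples = samples),
                    class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  fr <- c(spec$fraction_secondary, spec$fraction_obsolete,
          spec$fraction_foreign_taxon, spec$samples$multi_sample_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (spec$n_proteins < 0L) stop("n_proteins must be >= 0")
  if (diff(spec$length_range) < 0L || spec$length_range[1] < 30L) {
    stop("length_range must be increasing with minimum >= 30")
  }
  cc <- spec$category_counts
  counts <- c(cc$canonical_match, cc$isoform_match, cc$mismatch, cc$unmatched)
  if (any(counts < 0L)) stop("category counts must be >= 0")
  if (length(cc$offsets) && max(abs(cc$offsets)) >= spec$length_range[1]) {
    stop("planted offset magnitude exceeds the minimum sequence length")
  }
  if (length(cc$offsets) && any(cc$offsets == 0L)) {
    stop("planted offsets must be non-zero")
  }
  total <- sum(counts) + length(cc$offsets)
  if (total > spec$n_proteins) {
    stop("planted sites (", total, ") exceed available records (",
         spec$n_proteins, "); one site is planted per record")
  }
  if (any(spec$membership_vector < 0L)) stop("membership counts must be >= 0")
  invisible(spec)
}

random_sequence <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

#' Generate a synthetic sequence catalog with planted identifier outcomes
#'
#' Human primary records carry uniform random sequences and isoforms;
#' additional records of a foreign taxon, secondary accessions mapping to
#' human primaries, and obsolete accessions are generated according to the
#' spec's fractions (counts are `round(fraction * n_proteins)`). The truth
#' table records the harmonization outcome planted for every identifier.
#'
#' @param spec a `synthetic_spec`.
#' @return list with elements `catalog` (`sequence_catalog`) and `truth`
#'   (data.frame `accession`, `outcome`, `maps_to`).
#' @export
make_catalog <- function(spec) {
  validate_synthetic_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_proteins
  human <- sprintf("P%05d", seq_len(n))
  n_foreign <- round(spec$fraction_foreign_taxon * n)
  foreign <- sprintf("Q%05d", seq_len(n_foreign))
  n_sec <- round(spec$fraction_secondary * n)
  secondary <- sprintf("S%05d", seq_len(n_sec))
  n_obs <- round(spec$fraction_obsolete * n)
  obsolete <- sprintf("X%05d", seq_len(n_obs))

  gen_record <- function(acc, taxon) {
    len <- sample(spec$length_range[1]:spec$length_range[2], 1L)
    n_iso <- sample(spec$isoform_count_range[1]:spec$isoform_count_range[2], 1L)
    isoforms <- character()
    if (n_iso > 0L) {
      for (k in seq_len(n_iso)) {
        ilen <- max(30L, len + sample(-20:20, 1L))
        isoforms[paste0(acc, "-", k + 1L)] <- random_sequence(ilen)
      }
    }
    sequence_record(acc, random_sequence(len),
                    reviewed = stats::runif(1) > 0.2,
                    taxon = taxon, isoforms = isoforms)
  }
  records <- c(lapply(human, gen_record, taxon = 9606L),
               lapply(foreign, gen_record, taxon = 10090L))
  sec_map <- if (n_sec) {
    structure(sample(human, n_sec, replace = TRUE), names = secondary)
  } else character()

  catalog <- sequence_catalog(records, secondary_to_primary = sec_map,
                              obsolete = obsolete, reference_taxon = 9606L)
  truth <- data.frame(
    accession = c(human, foreign, secondary, obsolete),
    outcome = c(rep("primary", n), rep("taxon_dropped", n_foreign),
                rep("secondary_mapped", n_sec),
                rep("obsolete_dropped", n_obs)),
    maps_to = c(human, rep(NA_character_, n_foreign), unname(sec_map),
                rep(NA_character_, n_obs)),
    stringsAsFactors = FALSE)
  list(catalog = catalog, truth = truth)
}

#' Plant phosphosite annotations with known consistency categories
#'
#' One site is planted per human record, and the record's sequences are
#' edited so that the site's category under the documented classification
#' precedence is exactly the planted one: matches place the residue at the
#' position; isoform matches clear the canonical position and place the
#' residue in the first isoform; mismatches place a different
#' phosphorylatable residue and block all isoforms at that position; planted
#' offsets clear a window of radius |m| - 1 around the position (and the
#' equidistant tie position) before placing the residue at the planted
#' signed distance; unmatched sites sit beyond the canonical length with all
#' isoforms blocked. A final verification pass re-classifies every planted
#' site and fails loudly on any disagreement.
#'
#' @param catalog a `sequence_catalog` from [make_catalog()].
#' @param category_counts as in [synthetic_spec()].
#' @param seed integer seed.
#' @param residues phosphorylatable residue set.
#' @param name name for the generated annotation set.
#' @return list with elements `set` (the planted `annotation_set`), `truth`
#'   (data.frame `accession`, `residue`, `position`, `category`,
#'   `signed_offset`) and `catalog` (the edited catalog that classification
#'   must use).
#' @export
plant_sites <- function(catalog, category_counts, seed,
                        residues = phospho_residues(), name = "planted") {
  set.seed(seed)
  cc <- category_counts
  human <- names(catalog$records)[vapply(catalog$records, function(r)
    r$taxon == catalog$reference_taxon, logical(1))]
  plan <- c(rep("canonical_match", cc$canonical_match %||% 0L),
            rep("isoform_match", cc$isoform_match %||% 0L),
            rep("mismatch", cc$mismatch %||% 0L),
            rep("offset", length(cc$offsets %||% integer())),
            rep("unmatched", cc$unmatched %||% 0L))
  offsets <- as.integer(cc$offsets %||% integer())
  if (length(plan) > length(human)) {
    stop("not enough human records to plant one site per record")
  }
  hosts <- sample(human, length(plan))
  non_phospho <- setdiff(AA_ALPHABET, residues)

  truth <- vector("list", length(plan))
  off_i <- 0L
  for (i in seq_along(plan)) {
    acc <- hosts[i]
    rec <- catalog$records[[acc]]
    cv <- strsplit(rec$canonical, "", fixed = TRUE)[[1]]
    L <- length(cv)
    res <- sample(residues, 1L)
    filler <- sample(setdiff(non_phospho, res), 1L)
    category <- plan[i]
    signed <- NA_integer_

    if (category == "canonical_match") {
      pos <- sample.int(L, 1L)
      cv[pos] <- res
    } else if (category == "isoform_match") {
      if (!length(rec$isoforms)) {
        rec$isoforms <- stats::setNames(rec$canonical, paste0(acc, "-2"))
      }
      iso <- strsplit(rec$isoforms[[1]], "", fixed = TRUE)[[1]]
      pos <- sample.int(min(L, length(iso)), 1L)
      cv[pos] <- filler
      iso[pos] <- res
      rec$isoforms[[1]] <- paste(iso, collapse = "")
    } else if (category == "mismatch") {
      if (length(residues) < 2L) stop("mismatch planting needs >= 2 residues")
      pos <- sample.int(L, 1L)
      cv[pos] <- sample(setdiff(residues, res), 1L)
      rec$isoforms <- block_isoforms(rec$isoforms, pos, filler)
    } else if (category == "offset") {
      off_i <- off_i + 1L
      m <- offsets[off_i]
      lo <- max(1L, 1L + m)
      hi <- min(L, L + m)
      pos <- if (lo == hi) lo else sample(lo:hi, 1L)
      cv[pos] <- filler
      win <- setdiff(max(1L, pos - abs(m) + 1L):min(L, pos + abs(m) - 1L), pos)
      cv[win][cv[win] == res] <- filler
      opp <- pos + abs(m) * ifelse(m > 0L, 1L, -1L)
      if (opp >= 1L && opp <= L && cv[opp] == res) cv[opp] <- filler
      cv[pos - m] <- res
      rec$isoforms <- block_isoforms(rec$isoforms, pos, filler)
      signed <- m
    } else { # unmatched
      pos <- L + sample.int(30L, 1L)
      rec$isoforms <- block_isoforms(rec$isoforms, pos, filler)
    }
    rec$canonical <- paste(cv, collapse = "")
    catalog$records[[acc]] <- rec
    truth[[i]] <- data.frame(accession = acc, residue = res,
                             position = as.integer(pos), category = category,
                             signed_offset = signed, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, c(truth,
                            list(data.frame(accession = character(),
                                            residue = character(),
                                            position = integer(),
                                            category = character(),
                                            signed_offset = integer(),
                                            stringsAsFactors = FALSE))))
  verify_planted(catalog, truth, residues)
  set <- annotation_set(name, proteins = unique(truth$accession),
                        sites = site_table(truth$accession, truth$residue,
                                           truth$position))
  list(set = set, truth = truth, catalog = catalog)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# prevent any isoform from matching (or mismatching) at a planted position
block_isoforms <- function(isoforms, pos, filler) {
  for (id in names(isoforms)) {
    iso <- strsplit(isoforms[[id]], "", fixed = TRUE)[[1]]
    if (pos <= length(iso)) {
      iso[pos] <- filler
      isoforms[[id]] <- paste(iso, collapse = "")
    }
  }
  isoforms
}

verify_planted <- function(catalog, truth, residues) {
  for (i in seq_len(nrow(truth))) {
    got <- classify_site(truth[i, c("accession", "residue", "position")],
                         catalog$records[[truth$accession[i]]], residues)
    ok <- got$category == truth$category[i] &&
      (truth$category[i] != "offset" ||
         identical(got$signed_offset, truth$signed_offset[i]))
    if (!ok) {
      stop("planted-site verification failed for ", truth$accession[i], " ",
           truth$residue[i], "@", truth$position[i], ": planted ",
           truth$category[i], " (offset ", truth$signed_offset[i],
           "), classified ", got$category, " (offset ", got$signed_offset, ")")
    }
  }
  invisible(TRUE)
}

#' Generate named sets realizing a planted exclusive-intersection vector
#'
#' For each membership signature exactly the planted number of fresh
#' elements is created and inserted into the signature's sets, so
#' [exclusive_intersections()] on the output reproduces the vector
#' verbatim.
#'
#' @param names character vector of set names.
#' @param membership_vector named integer vector; names are `&`-joined
#'   non-empty subsets of `names`.
#' @param seed integer seed (controls element shuffling only).
#' @param elements optional pool of element ids to draw from (at least
#'   `sum(membership_vector)`); defaults to generated ids.
#' @return list with `sets` (named list of character vectors) and `truth`
#'   (data.frame `element`, `signature` with canonically ordered
#'   signatures).
#' @export
make_membership <- function(names, membership_vector, seed, elements = NULL) {
  set.seed(seed)
  if (!length(membership_vector)) {
    return(list(sets = stats::setNames(rep(list(character()), length(names)),
                                       names),
                truth = data.frame(element = character(),
                                   signature = character(),
                                   stringsAsFactors = FALSE)))
  }
  total <- sum(membership_vector)
  if (is.null(elements)) {
    elements <- sprintf("M%06d", seq_len(total))
  }
  if (length(elements) < total) stop("element pool smaller than planted total")
  elements <- sample(elements, total)

  sig_members <- strsplit(base::names(membership_vector), "&", fixed = TRUE)
  for (s in sig_members) {
    if (!length(s) || length(setdiff(s, names))) {
      stop("membership signature uses unknown or empty set names")
    }
  }
  canon <- vapply(sig_members, function(s)
    paste(names[sort(match(s, names))], collapse = "&"), character(1))

  sets <- stats::setNames(rep(list(character()), length(names)), names)
  truth <- vector("list", length(membership_vector))
  used <- 0L
  for (j in seq_along(membership_vector)) {
    k <- membership_vector[[j]]
    if (!k) {
      truth[[j]] <- data.frame(element = character(), signature = character(),
                               stringsAsFactors = FALSE)
      next
    }
    el <- elements[used + seq_len(k)]
    used <- used + k
    for (s in sig_members[[j]]) sets[[s]] <- c(sets[[s]], el)
    truth[[j]] <- data.frame(element = el, signature = canon[j],
                             stringsAsFactors = FALSE)
  }
  list(sets = lapply(sets, sort), truth = do.call(rbind, truth))
}

#' Generate a qPhos-style experimental table with planted sample labels
#'
#' Publications (PMIDs) are assigned one cell-line label each according to
#' `samples$pmids_per_sample`; a planted fraction of them receives a second
#' label, making them multi-sample and hence excluded by
#' [filter_single_sample()]. Each PMID reports `sites_per_pmid` sites drawn
#' from the supplied pool.
#'
#' @param samples as in [synthetic_spec()] (`labels`, `pmids_per_sample`,
#'   `sites_per_pmid`, `multi_sample_fraction`).
#' @param site_pool site data.frame to draw reported sites from.
#' @param seed integer seed.
#' @return list with `records` (an `experimental_records` object) and
#'   `truth` (list `pmid_samples`, `single_pmids`, `multi_pmids`,
#'   `primary_label` named by PMID).
#' @export
make_experimental <- function(samples, site_pool, seed) {
  set.seed(seed)
  if (!nrow(site_pool)) stop("site pool must be non-empty")
  labels <- samples$labels
  per <- rep(samples$pmids_per_sample, length.out = length(labels))
  total <- sum(per)
  pmids <- sprintf("PM%06d", seq_len(total))
  primary <- rep(labels, per)

  n_multi <- round(samples$multi_sample_fraction * total)
  if (n_multi > 0L && length(labels) < 2L) {
    stop("multi-sample PMIDs need at least two labels")
  }
  multi_idx <- if (n_multi) sample.int(total, n_multi) else integer()
  pmid_samples <- stats::setNames(as.list(primary), pmids)
  for (i in multi_idx) {
    extra <- sample(setdiff(labels, primary[i]), 1L)
    pmid_samples[[i]] <- c(primary[i], extra)
  }

  k <- min(samples$sites_per_pmid, nrow(site_pool))
  rows <- lapply(seq_len(total), function(i) {
    picked <- site_pool[sample.int(nrow(site_pool), k), , drop = FALSE]
    data.frame(accession = picked$accession, residue = picked$residue,
               position = picked$position, pmid = pmids[i],
               stringsAsFactors = FALSE)
  })
  records <- experimental_records(do.call(rbind, rows), pmid_samples)
  truth <- list(pmid_samples = lapply(pmid_samples, sort),
                single_pmids = sort(pmids[setdiff(seq_len(total), multi_idx)]),
                multi_pmids = sort(pmids[multi_idx]),
                primary_label = stats::setNames(primary, pmids))
  list(records = records, truth = truth)
}

#' Generate a complete synthetic study on disk
#'
#' Writes everything a full audit run ingests: the catalog FASTA and
#' id-status table, one annotation TSV per membership database (protein
#' membership drawn from unused human accessions, so the sets pass
#' harmonization unchanged), a site-bearing annotation TSV realizing the
#' planted consistency categories, an identifier-audit TSV listing every
#' catalog identifier (whose harmonization report recovers the planted
#' outcome fractions), an experimental TSV, and the planted truth as JSON.
#'
#' @param spec a `synthetic_spec`.
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the generated objects, the truth, and the
#'   file paths.
#' @export
simulate_study <- function(spec, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cat_gen <- make_catalog(spec)
  planted <- plant_sites(cat_gen$catalog, spec$category_counts,
                         seed = spec$seed + 1L)
  catalog <- planted$catalog

  human <- cat_gen$truth$accession[cat_gen$truth$outcome == "primary"]
  free <- setdiff(human, planted$truth$accession)
  membership <- make_membership(spec$membership_names, spec$membership_vector,
                                seed = spec$seed + 2L, elements = free)
  experimental <- make_experimental(spec$samples, planted$set$sites,
                                    seed = spec$seed + 3L)

  paths <- list(fasta = file.path(out_dir, "catalog.fasta"),
                ids = file.path(out_dir, "catalog_ids.tsv"),
                sites = file.path(out_dir, "sites.tsv"),
                id_audit = file.path(out_dir, "id_audit.tsv"),
                experimental = file.path(out_dir, "experimental.tsv"),
                truth = file.path(out_dir, "truth.json"))
  write_catalog(catalog, paths$fasta, paths$ids)
  write_annotation_set(planted$set, paths$sites)
  write_annotation_set(annotation_set("id_audit",
                                      proteins = cat_gen$truth$accession),
                       paths$id_audit)
  for (nm in names(membership$sets)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_annotation_set(annotation_set(nm, proteins = membership$sets[[nm]]),
                         p)
    paths[[nm]] <- p
  }
  write_experimental(experimental$records, paths$experimental)

  truth <- list(identifier = cat_gen$truth, sites = planted$truth,
                membership = membership$truth,
                membership_vector = as.list(spec$membership_vector),
                experimental = experimental$truth)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(list(spec = spec, catalog = catalog, planted = planted,
                 membership = membership, experimental = experimental,
                 truth = truth, paths = paths))
}
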