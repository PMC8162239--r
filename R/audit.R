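#' Configuration for a full audit run
#'
#' @param catalog_fasta,catalog_ids paths to the reference catalog FASTA and
#'   id-status TSV.
#' @param databases named character vector of annotation TSV paths, one per
#'   resource.
#' @param experimental optional path to a qPhos-style experimental TSV.
#' @param term_map optional path to a term-to-protein map (two-column TSV).
#' @param reference_taxon reference organism taxon id.
#' @param residues phosphorylatable residue set.
#' @param level set-algebra level for coverage tables.
#' @param min_subset_size display filter for the UpSet table written to
#'   disk; stored counts always include every signature when 0.
#' @param alpha ORA significance level.
#' @param top_k number of top-ranked samples kept in the experimental
#'   coverage matrices (`NULL` for all).
#' @param out_dir output directory for report tables.
#' @return a validated list of class `audit_config`; all referenced paths
#'   must exist.
#' @export
audit_config <- function(catalog_fasta, catalog_ids, databases,
                         experimental = NULL, term_map = NULL,
                         reference_taxon = 9606L,
                         residues = phospho_residues(),
                         level = c("protein", "site"),
                         min_subset_size = 0L, alpha = 0.05, top_k = 6L,
                         out_dir) {
  level <- match.arg(level)
  if (is.null(names(databases)) || any(!nzchar(names(databases)))) {
    stop("databases must be a named vector of paths")
  }
  paths <- c(catalog_fasta, catalog_ids, unname(databases), experimental,
             term_map)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input path(s) do not exist: ", paste(missing, collapse = ", "))
  }
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (min_subset_size < 0L) stop("min_subset_size must be >= 0")
  structure(list(catalog_fasta = catalog_fasta, catalog_ids = catalog_ids,
                 databases = databases, experimental = experimental,
                 term_map = term_map,
                 reference_taxon = as.integer(reference_taxon),
                 residues = residues, level = level,
                 min_subset_size = as.integer(min_subset_size),
                 alpha = alpha, top_k = top_k, out_dir = out_dir),
            class = "audit_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("audit stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full annotation audit
#'
#' Executes harmonize, consistency, coverage, experimental and enrichment
#' stages over the configured inputs and writes the combined report: one
#' harmonization table per database, the per-database consistency summary
#' (audit-table layout), pairwise intersection / exclusive-intersection /
#' unique-set / set-difference tables, the per-sample coverage matrices at
#' protein and site level, the enrichment table for each database's unique
#' proteins, and a machine-readable manifest (package version, input
#' checksums). Any stage failure aborts with a stage-named error and no
#' report files are left behind.
#'
#' @param config an `audit_config`.
#' @return invisibly, a list with every stage's in-memory results and the
#'   written file paths.
#' @export
run_audit <- function(config) {
  stopifnot(inherits(config, "audit_config"))
  catalog <- stage("read_catalog", read_catalog(config$catalog_fasta,
                                                config$catalog_ids,
                                                config$reference_taxon))
  raw_sets <- stage("read_annotations", lapply(names(config$databases),
    function(nm) read_annotation_set(config$databases[[nm]], nm)))

  harmonized <- stage("harmonize",
                      lapply(raw_sets, harmonize_annotation_set, catalog))
  names(harmonized) <- names(config$databases)
  sets <- lapply(harmonized, `[[`, "set")

  consistency <- stage("consistency", {
    lapply(sets, function(s) {
      if (!nrow(s$sites)) return(NULL)
      summarize_consistency(classify_sites(s, catalog, config$residues))
    })
  })

  prot_sets <- element_sets(sets, "protein")
  lvl_sets <- element_sets(sets, config$level)
  coverage <- stage("coverage", list(
    pairwise = pairwise_matrix(lvl_sets, lvl_sets),
    upset = exclusive_intersections(lvl_sets),
    unique = stats::setNames(lapply(names(lvl_sets), unique_elements,
                                    lvl_sets), names(lvl_sets)),
    differences = difference_matrix(lvl_sets, lvl_sets)))

  experimental <- NULL
  if (!is.null(config$experimental)) {
    experimental <- stage("experimental", {
      rec <- read_experimental(config$experimental)
      flt <- filter_single_sample(rec)
      list(records = rec, kept = flt$kept, excluded = flt$excluded,
           ranking = rank_samples(flt$kept),
           protein = sample_coverage(flt$kept, sets, "protein",
                                     top_k = config$top_k),
           site = sample_coverage(flt$kept, sets, "site",
                                  top_k = config$top_k))
    })
  }

  enrichment <- NULL
  if (!is.null(config$term_map)) {
    enrichment <- stage("enrichment", {
      term_map <- read_term_map(config$term_map)
      background <- unique(unlist(prot_sets, use.names = FALSE))
      res <- lapply(names(prot_sets), function(nm) {
        uq <- unique_elements(nm, prot_sets)
        out <- ora(uq, background, term_map, config$alpha)
        if (nrow(out)) cbind(database = nm, out, stringsAsFactors = FALSE)
        else NULL
      })
      do.call(rbind, res)
    })
  }

  files <- stage("write_report",
                 write_audit_report(config, harmonized, consistency, coverage,
                                    experimental, enrichment))
  invisible(list(catalog = catalog, harmonized = harmonized,
                 consistency = consistency, coverage = coverage,
                 experimental = experimental, enrichment = enrichment,
                 files = files))
}

write_audit_report <- function(config, harmonized, consistency, coverage,
                               experimental, enrichment) {
  out_dir <- config$out_dir
  tables <- list()

  tables$harmonization <- do.call(rbind, lapply(names(harmonized),
    function(nm) {
      fr <- harmonization_fractions(harmonized[[nm]]$report)
      cbind(database = nm, fr, stringsAsFactors = FALSE)
    }))

  cons_rows <- lapply(names(consistency), function(nm) {
    if (is.null(consistency[[nm]])) return(NULL)
    consistency_summary_row(consistency[[nm]], nm)
  })
  cons_rows <- cons_rows[!vapply(cons_rows, is.null, logical(1))]
  if (length(cons_rows)) tables$consistency <- do.call(rbind, cons_rows)

  tables$pairwise <- matrix_to_long(coverage$pairwise$count,
                                    coverage$pairwise$proportion)
  up <- coverage$upset
  up_out <- if (config$min_subset_size > 0L)
    up[up$count >= config$min_subset_size, , drop = FALSE] else up
  tables$upset <- as.data.frame(up_out)
  tables$unique_sets <- do.call(rbind, lapply(names(coverage$unique),
    function(nm) {
      el <- coverage$unique[[nm]]
      if (!length(el)) return(NULL)
      data.frame(database = nm, element = el, stringsAsFactors = FALSE)
    }))
  tables$difference_ref_minus_query <-
    count_matrix_to_long(coverage$differences$ref_minus_query)
  tables$difference_query_minus_ref <-
    count_matrix_to_long(coverage$differences$query_minus_ref)

  if (!is.null(experimental)) {
    tables$sample_ranking <- experimental$ranking
    tables$sample_coverage_protein <-
      matrix_to_long(experimental$protein$count,
                     experimental$protein$proportion,
                     row_name = "sample", col_name = "database")
    tables$sample_coverage_site <-
      matrix_to_long(experimental$site$count, experimental$site$proportion,
                     row_name = "sample", col_name = "database")
  }
  if (!is.null(enrichment) && nrow(enrichment)) {
    tables$enrichment <- enrichment
  }
  tables <- tables[!vapply(tables, is.null, logical(1))]

  files <- write_tables(tables, out_dir)
  manifest <- list(
    package = "phosphoaudit",
    version = as.character(utils::packageVersion("phosphoaudit")),
    level = config$level, alpha = config$alpha,
    min_subset_size = config$min_subset_size,
    residues = config$residues,
    reference_taxon = config$reference_taxon,
    inputs = input_checksums(config),
    tables = basename(files))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  c(files, manifest_path)
}

input_checksums <- function(config) {
  paths <- c(catalog_fasta = config$catalog_fasta,
             catalog_ids = config$catalog_ids, config$databases)
  if (!is.null(config$experimental)) {
    paths <- c(paths, experimental = config$experimental)
  }
  if (!is.null(config$term_map)) paths <- c(paths, term_map = config$term_map)
  as.list(tools::md5sum(paths))
}

matrix_to_long <- function(count, proportion, row_name = "reference",
                           col_name = "query") {
  if (!length(count)) {
    out <- data.frame(a = character(), b = character(), count = integer(),
                      proportion = numeric(), stringsAsFactors = FALSE)
    names(out)[1:2] <- c(row_name, col_name)
    return(out)
  }
  out <- data.frame(a = rep(rownames(count), ncol(count)),
                    b = rep(colnames(count), each = nrow(count)),
                    count = as.integer(count),
                    proportion = as.numeric(proportion),
                    stringsAsFactors = FALSE)
  names(out)[1:2] <- c(row_name, col_name)
  out
}

count_matrix_to_long <- function(count) {
  if (!length(count)) {
    return(data.frame(reference = character(), query = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  data.frame(reference = rep(rownames(count), ncol(count)),
             query = rep(colnames(count), each = nrow(count)),
             count = as.integer(count), stringsAsFactors = FALSE)
}
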