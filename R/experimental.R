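#' Filter experimental records to single-sample publications
#'
#' When a publication (PMID) is tagged with several sample labels it is
#' impossible to discern which modification came from which sample, so only
#' PMIDs carrying exactly one label are analysed. Filtering is applied at
#' PMID granularity: all of a multi-sample PMID's records are excluded
#' together.
#'
#' @param records an `experimental_records` object.
#' @return list with elements `kept` and `excluded`, both
#'   `experimental_records`; their record rows partition the input.
#' @export
filter_single_sample <- function(records) {
  single <- names(records$pmid_samples)[lengths(records$pmid_samples) == 1L]
  split_records(records, single)
}

split_records <- function(records, keep_pmids) {
  df <- records$records
  in_keep <- df$pmid %in% keep_pmids
  mk <- function(rows, pmids) {
    experimental_records(df[rows, , drop = FALSE],
                         records$pmid_samples[names(records$pmid_samples)
                                              %in% pmids])
  }
  all_pmids <- names(records$pmid_samples)
  list(kept = mk(in_keep, keep_pmids),
       excluded = mk(!in_keep, setdiff(all_pmids, keep_pmids)))
}

#' Rank samples by number of distinct publications
#'
#' @param records single-sample-filtered `experimental_records`.
#' @return data.frame with columns `sample` and `n_pmids`, sorted by
#'   descending publication count, ties broken by sample name ascending.
#' @export
rank_samples <- function(records) {
  multi <- names(records$pmid_samples)[lengths(records$pmid_samples) > 1L]
  if (length(multi)) {
    stop("rank_samples expects single-sample-filtered records; PMID(s) with ",
         "multiple samples present: ", paste(utils::head(multi, 3),
                                             collapse = ", "))
  }
  sample_of <- vapply(records$pmid_samples, `[`, character(1), 1L)
  tab <- table(sample_of)
  out <- data.frame(sample = names(tab), n_pmids = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_pmids, out$sample), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample database coverage of experimental phosphoproteomes
#'
#' For each sample (cell line) the measured set is the distinct protein
#' bases (protein level) or site triples (site level) among that sample's
#' records; a protein is "measured" in a sample iff at least one of its
#' sites is. Each cell is the intersection of the sample's measured set
#' with one database's protein or site set, expressed also as a proportion
#' of the sample's set. Rows are ordered by descending publication count,
#' then name; columns follow the database list.
#'
#' @param records single-sample-filtered `experimental_records`.
#' @param databases list of harmonized `annotation_set` objects.
#' @param level `"protein"` or `"site"`.
#' @param top_k optionally restrict to the top `top_k` samples by
#'   publication count.
#' @return an object of class `sample_coverage_matrix`: list with matrices
#'   `count` and `proportion` (rows = samples, columns = databases) and the
#'   data.frame `samples` (sample, n_pmids, set_size).
#' @export
sample_coverage <- function(records, databases, level = c("protein", "site"),
                            top_k = NULL) {
  level <- match.arg(level)
  ranking <- rank_samples(records)
  if (!is.null(top_k)) ranking <- utils::head(ranking, top_k)
  db_sets <- element_sets(databases, level)

  sample_of <- vapply(records$pmid_samples, `[`, character(1), 1L)
  df <- records$records
  rec_sample <- unname(sample_of[df$pmid])

  sample_set <- function(s) {
    rows <- df[rec_sample == s, , drop = FALSE]
    if (level == "protein") unique(rows$accession)
    else unique(site_key(rows))
  }
  sets <- lapply(ranking$sample, sample_set)
  names(sets) <- ranking$sample

  cnt <- matrix(0L, nrow = length(sets), ncol = length(db_sets),
                dimnames = list(names(sets), names(db_sets)))
  prop <- matrix(0, nrow = nrow(cnt), ncol = ncol(cnt),
                 dimnames = dimnames(cnt))
  for (s in seq_along(sets)) {
    for (d in seq_along(db_sets)) {
      n <- sum(sets[[s]] %in% db_sets[[d]])
      cnt[s, d] <- n
      prop[s, d] <- if (length(sets[[s]])) n / length(sets[[s]]) else 0
    }
  }
  ranking$set_size <- lengths(sets)
  structure(list(count = cnt, proportion = prop, samples = ranking),
            class = "sample_coverage_matrix")
}

#' @export
print.sample_coverage_matrix <- function(x, ...) {
  cat("sample_coverage_matrix (", nrow(x$count), " samples x ",
      ncol(x$count), " databases)\n", sep = "")
  print(round(x$proportion, 3))
  invisible(x)
}
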