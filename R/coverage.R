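#' Pairwise intersection / coverage matrix
#'
#' Each cell holds the size of the intersection between one reference set
#' (row) and one query set (column), together with the proportion of the
#' reference it represents — the "coverage" of the reference by the query.
#'
#' @param query_sets,reference_sets named lists of character vectors
#'   (protein bases or site keys, see [site_key()]).
#' @return an object of class `coverage_matrix`: list with integer matrix
#'   `count` and numeric matrix `proportion` (rows = references, columns =
#'   queries; proportion is 0 for an empty reference).
#' @export
pairwise_matrix <- function(query_sets, reference_sets) {
  query_sets <- lapply(query_sets, unique)
  reference_sets <- lapply(reference_sets, unique)
  cnt <- matrix(0L, nrow = length(reference_sets), ncol = length(query_sets),
                dimnames = list(names(reference_sets), names(query_sets)))
  prop <- matrix(0, nrow = nrow(cnt), ncol = ncol(cnt),
                 dimnames = dimnames(cnt))
  for (r in seq_along(reference_sets)) {
    ref <- reference_sets[[r]]
    for (q in seq_along(query_sets)) {
      n <- sum(ref %in% query_sets[[q]])
      cnt[r, q] <- n
      prop[r, q] <- if (length(ref)) n / length(ref) else 0
    }
  }
  structure(list(count = cnt, proportion = prop), class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat("coverage_matrix (", nrow(x$count), " references x ", ncol(x$count),
      " queries)\n", sep = "")
  print(x$count)
  invisible(x)
}

#' Exclusive (UpSet-style) intersections
#'
#' Every element of the union is assigned to exactly the subset of set names
#' that contain it; the table of counts per membership signature partitions
#' the union, so the counts always sum to the union size. An optional
#' minimum-count filter is a display convenience applied only to the
#' returned table, mirroring the practice of hiding small overlaps in
#' plotted UpSets; stored tables should use the default of 0.
#'
#' @param sets named list (>= 1) of character vectors.
#' @param min_count drop signatures with fewer elements from the output.
#' @return an object of class `exclusive_intersections`: data.frame with
#'   columns `signature` (set names joined by `&` in input order) and
#'   `count`, with attributes `universe_size` and `set_names`.
#' @export
exclusive_intersections <- function(sets, min_count = 0L) {
  if (!length(sets) || is.null(names(sets))) {
    stop("need at least one named set")
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  nm <- names(sets)
  if (length(universe)) {
    member <- vapply(sets, function(s) universe %in% s,
                     logical(length(universe)))
    member <- matrix(member, nrow = length(universe),
                     dimnames = list(NULL, nm))
    sig <- apply(member, 1L, function(row) paste(nm[row], collapse = "&"))
    tab <- table(sig)
    out <- data.frame(signature = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(signature = character(), count = integer(),
                      stringsAsFactors = FALSE)
  }
  stopifnot(sum(out$count) == length(universe))
  out <- out[order(-out$count, out$signature), , drop = FALSE]
  rownames(out) <- NULL
  full <- structure(out, universe_size = length(universe), set_names = nm,
                    class = c("exclusive_intersections", "data.frame"))
  if (min_count > 0L) {
    kept <- full[full$count >= min_count, , drop = FALSE]
    attr(kept, "universe_size") <- length(universe)
    attr(kept, "set_names") <- nm
    rownames(kept) <- NULL
    return(kept)
  }
  full
}

#' Elements unique to one named set
#'
#' @param name the set whose exclusive elements are wanted.
#' @param sets named list of character vectors.
#' @return character vector of elements found in `name` and in no other set.
#' @export
unique_elements <- function(name, sets) {
  if (!name %in% names(sets)) stop("unknown set name: ", name)
  others <- unique(unlist(sets[setdiff(names(sets), name)], use.names = FALSE))
  sort(setdiff(unique(sets[[name]]), others))
}

#' Set-difference matrices between references and queries
#'
#' @param query_sets,reference_sets named lists of character vectors.
#' @return list of two integer matrices: `ref_minus_query` with cell (r, q)
#'   = |reference_r \ query_q|, and `query_minus_ref`, its transposed
#'   orientation with cell (r, q) = |query_q \ reference_r|.
#' @export
difference_matrix <- function(query_sets, reference_sets) {
  query_sets <- lapply(query_sets, unique)
  reference_sets <- lapply(reference_sets, unique)
  rmq <- matrix(0L, nrow = length(reference_sets), ncol = length(query_sets),
                dimnames = list(names(reference_sets), names(query_sets)))
  qmr <- rmq
  for (r in seq_along(reference_sets)) {
    for (q in seq_along(query_sets)) {
      rmq[r, q] <- length(setdiff(reference_sets[[r]], query_sets[[q]]))
      qmr[r, q] <- length(setdiff(query_sets[[q]], reference_sets[[r]]))
    }
  }
  list(ref_minus_query = rmq, query_minus_ref = qmr)
}

#' Extract element sets from annotation sets at a chosen level
#'
#' @param sets list of `annotation_set` objects.
#' @param level `"protein"` for base accessions or `"site"` for
#'   accession|residue|position keys.
#' @return named list of character vectors keyed by resource name.
#' @export
element_sets <- function(sets, level = c("protein", "site")) {
  level <- match.arg(level)
  out <- lapply(sets, function(s) {
    if (level == "protein") s$proteins else site_key(s$sites)
  })
  names(out) <- vapply(sets, function(s) s$name, character(1))
  out
}
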