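#' Over-representation analysis of a protein set
#'
#' Tests each term of a term-to-protein map for enrichment in the query set
#' relative to a background, using the one-sided hypergeometric upper tail
#' (the standard ORA formulation): with `N` background proteins, `K` of
#' them in the term, and a query of size `n` containing `k` term members,
#' `p = P[X >= k]` for `X ~ Hypergeometric(N, K, n)`. Raw p values are
#' adjusted across tested terms with Benjamini-Hochberg, and both are
#' reported so either reading is available.
#'
#' @param query character vector of proteins; must be a subset of
#'   `background`.
#' @param background character vector of background proteins (e.g. the
#'   union of all databases' proteins).
#' @param term_map named list mapping term ids to character vectors of
#'   proteins; members outside the background are ignored.
#' @param alpha significance level applied to the adjusted values for the
#'   `significant` flag.
#' @return data.frame sorted by p with columns `term`, `k`, `K`, `n`, `N`,
#'   `p`, `q`, `significant`. Terms with no background member are dropped.
#' @export
ora <- function(query, background, term_map, alpha = 0.05) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  if (length(setdiff(query, background))) {
    stop("query contains proteins absent from the background: ",
         paste(utils::head(setdiff(query, background), 5), collapse = ", "))
  }
  if (!length(term_map)) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(term_map))) stop("term_map must be named by term id")
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(term_map), function(term) {
    members <- intersect(unique(as.character(term_map[[term]])), background)
    K <- length(members)
    if (!K) return(NULL)
    k <- length(intersect(members, query))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q <= alpha
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a term-to-protein map
#'
#' Accepts either a two-column TSV (`term`, `accession`) or a GMT-style file
#' (term, description, members... separated by tabs, no header).
#'
#' @param path path to the map file.
#' @param format `"tsv"` or `"gmt"`.
#' @return named list of character vectors keyed by term id.
#' @export
read_term_map <- function(path, format = c("tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, colClasses = "character",
                             stringsAsFactors = FALSE)
    if (!all(c("term", "accession") %in% names(tab))) {
      stop("term map TSV needs columns 'term' and 'accession'")
    }
    lapply(split(tab$accession, tab$term), unique)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(parts) < 3L
    if (any(bad)) stop("GMT line ", which(bad)[1], " has fewer than 3 fields")
    stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                    vapply(parts, `[`, character(1), 1L))
  }
}
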