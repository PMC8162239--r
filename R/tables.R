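#' Write result tables deterministically as TSV plus a JSON mirror
#'
#' Every summary table the pipeline emits goes through this writer: rows are
#' sorted on all columns, column order is preserved, and each table is
#' written both as a TSV and as a JSON mirror with identical content, so two
#' runs on the same input produce byte-identical files.
#'
#' @param results named list of data.frames.
#' @param out_dir output directory, created if needed.
#' @return invisibly, a character vector of the files written.
#' @export
write_tables <- function(results, out_dir) {
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    stop("every result table must be named")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  }
  written <- character()
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]], stringsAsFactors = FALSE)
    df <- sort_rows(df)
    tsv <- file.path(out_dir, paste0(nm, ".tsv"))
    json <- file.path(out_dir, paste0(nm, ".json"))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(df, json, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
    written <- c(written, tsv, json)
  }
  invisible(written)
}

# deterministic row order: sort on all columns left to right
sort_rows <- function(df) {
  if (!nrow(df) || !ncol(df)) return(df)
  o <- do.call(order, unname(as.list(df)))
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}
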