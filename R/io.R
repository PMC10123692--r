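# Tab-separated interchange formats for expression profiles, metabolite
# time series, exchange bounds and reduction reports.

#' Read an expression profile from TSV
#'
#' Expected layout: a `gene_id` column followed by one numeric column per
#' replicate.
#'
#' @param path TSV file.
#' @return numeric matrix, genes x replicates.
#' @export
readExpressionTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) stop("expected a 'gene_id' column in ", path)
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

#' Write an expression profile to TSV
#'
#' @param mat genes x replicates matrix with rownames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeExpressionTSV <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read metabolite time-series measurements from TSV
#'
#' Columns: `metabolite`, `compartment` (`medium`/`cell`), `c0`, `Sd0`,
#' `c5`, `Sd5` (extra columns are preserved).
#'
#' @param path TSV file.
#' @return data.frame suitable for [metaboliteBounds()].
#' @export
readMetaboliteTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "c0", "Sd0", "c5", "Sd5")
  if (!all(need %in% names(df))) {
    stop("metabolite TSV must contain columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Write a data.frame as TSV
#'
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a model-reduction report as TSV
#'
#' One row per removed entity with its removal reason (`blocked` /
#' `empty-stoichiometry` / `dead-end-metabolite`).
#'
#' @param report report list from [reduceModel()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReductionReport <- function(report, path) {
  df <- rbind(
    data.frame(id = report$removed_blocked, reason = "blocked",
               stringsAsFactors = FALSE),
    data.frame(id = report$removed_dead_end, reason = "dead-end-metabolite",
               stringsAsFactors = FALSE))
  writeTSV(df, path)
}
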