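#' Read a count matrix and sample metadata from TSV
#'
#' Expects the fixture dialect written by [writeFixture()]: a counts table
#' whose first two columns are \code{gene_id} and \code{length_bp} followed
#' by one integer column per sample, and a metadata table with columns
#' \code{sample_id}, \code{species}, \code{tissue}, \code{individual},
#' \code{date} (ISO-8601).
#'
#' @param countsPath,metaPath file paths.
#' @return a validated \linkS4class{PhenologyExperiment}.
#' @export
readExpressionTsv <- function(countsPath, metaPath) {
  cntDf <- utils::read.delim(countsPath, check.names = FALSE,
                             stringsAsFactors = FALSE)
  if (!identical(colnames(cntDf)[1:2], c("gene_id", "length_bp")))
    stop("malformed counts header: expected 'gene_id' and 'length_bp' first")
  dup <- cntDf$gene_id[duplicated(cntDf$gene_id)]
  if (length(dup))
    stop("duplicated gene ID(s): ", paste(unique(dup), collapse = ", "))
  meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
  need <- c("sample_id", "species", "tissue", "individual", "date")
  if (!all(need %in% colnames(meta)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  sampleCols <- setdiff(colnames(cntDf), c("gene_id", "length_bp"))
  missing <- setdiff(sampleCols, meta$sample_id)
  if (length(missing))
    stop("no metadata row for sample(s): ", paste(missing, collapse = ", "))
  cnt <- as.matrix(cntDf[, sampleCols, drop = FALSE])
  if (!is.numeric(cnt) || any(abs(cnt - round(cnt)) > 1e-8, na.rm = TRUE))
    stop("count columns must be integer-valued")
  rownames(cnt) <- cntDf$gene_id
  meta <- meta[match(sampleCols, meta$sample_id), ]
  meta$date <- as.Date(meta$date)
  if (anyNA(meta$date)) stop("metadata dates must be ISO-8601 (YYYY-MM-DD)")
  PhenologyExperiment(cnt, cntDf$length_bp,
                      meta[, c("species", "tissue", "individual", "date")])
}

#' Write or read a normalized expression matrix as TSV
#'
#' The file carries a `# molphen getmm v1` marker line ahead of the header so
#' normalized matrices are distinguishable from raw-count fixtures.
#'
#' @param mat numeric matrix (genes x columns) with dimnames.
#' @param path output file.
#' @return \code{writeNormalizedTsv}: invisibly, \code{path};
#'   \code{readNormalizedTsv}: the matrix.
#' @export
writeNormalizedTsv <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# molphen getmm v1", con)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNormalizedTsv
#' @export
readNormalizedTsv <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# molphen getmm"))
    stop("not a molphen normalized matrix: ", path)
  df <- utils::read.delim(path, skip = 1, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene_id
  mat
}
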