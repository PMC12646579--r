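#' Construct a PhenologyExperiment
#'
#' @param counts gene-by-sample matrix of non-negative integer counts with
#'   unique rownames (gene IDs) and colnames (sample IDs).
#' @param geneLengths numeric vector of gene lengths in bp, one per row of
#'   \code{counts} (recycled from a named vector by gene ID if named).
#' @param sampleData data.frame with one row per sample column and columns
#'   \code{species}, \code{tissue}, \code{individual}, \code{date}
#'   (\code{Date} or ISO-8601 strings).
#' @return a \linkS4class{PhenologyExperiment}.
#' @examples
#' cnt <- matrix(rpois(12, 50), 3, 4,
#'               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(species = "A", tissue = "bud", individual = 1,
#'                    date = as.Date("2021-04-15") + 28 * (0:3))
#' pe <- PhenologyExperiment(cnt, c(1000, 2000, 500), meta)
#' @export
PhenologyExperiment <- function(counts, geneLengths, sampleData) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("counts must have gene IDs as rownames")
  if (!is.null(names(geneLengths)))
    geneLengths <- geneLengths[rownames(counts)]
  if (length(geneLengths) != nrow(counts))
    stop("geneLengths must match the number of genes")
  sampleData <- as.data.frame(sampleData)
  if (nrow(sampleData) != ncol(counts))
    stop("sampleData must have one row per sample column")
  if (!inherits(sampleData$date, "Date"))
    sampleData$date <- as.Date(sampleData$date)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(length_bp = as.numeric(geneLengths)),
    colData = S4Vectors::DataFrame(sampleData)
  )
  methods::new("PhenologyExperiment", se)
}

#' @describeIn PhenologyExperiment gene lengths in bp.
#' @param x a \code{PhenologyExperiment}.
#' @export
geneLengths <- function(x) {
  SummarizedExperiment::rowData(x)$length_bp
}

#' @describeIn PhenologyExperiment sampling dates, one per sample.
#' @export
sampleDates <- function(x) {
  SummarizedExperiment::colData(x)$date
}

#' @describeIn PhenologyExperiment species label per sample.
#' @export
sampleSpecies <- function(x) {
  as.character(SummarizedExperiment::colData(x)$species)
}

setMethod("show", "PhenologyExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("PhenologyExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  species:", paste(unique(cd$species), collapse = ", "), "\n")
  cat("  tissues:", paste(unique(cd$tissue), collapse = ", "), "\n")
  if (nrow(cd))
    cat("  dates:  ", format(min(cd$date)), "to", format(max(cd$date)), "\n")
  invisible(NULL)
})
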