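#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Container for seasonal expression count data
#'
#' A \code{PhenologyExperiment} holds a gene-by-sample matrix of raw RNA-seq
#' counts together with per-gene lengths (\code{rowData} column
#' \code{length_bp}) and per-sample metadata (\code{colData} columns
#' \code{species}, \code{tissue}, \code{individual}, \code{date}). It is the
#' entry point of the molecular-phenology pipeline.
#'
#' @slot .. inherits all slots from
#'   \linkS4class{SummarizedExperiment}.
#' @seealso [PhenologyExperiment()] for the constructor, [geneLengths()],
#'   [sampleDates()].
#' @export
setClass("PhenologyExperiment", contains = "SummarizedExperiment")

setValidity("PhenologyExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(cnt)) msg <- c(msg, "counts must not contain NA")
    else if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
    else if (any(abs(cnt - round(cnt)) > 1e-8))
      msg <- c(msg, "counts must be integer-valued")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene IDs (rownames) must be present and unique")
  rd <- SummarizedExperiment::rowData(object)
  if (!"length_bp" %in% colnames(rd))
    msg <- c(msg, "rowData must contain 'length_bp'")
  else if (any(!is.finite(rd$length_bp)) || any(rd$length_bp <= 0))
    msg <- c(msg, "gene lengths must be positive and finite")
  cd <- SummarizedExperiment::colData(object)
  need <- c("species", "tissue", "individual", "date")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData must contain: ", paste(miss, collapse = ", ")))
  else if (!inherits(cd$date, "Date"))
    msg <- c(msg, "colData$date must be of class Date")
  if (length(msg)) msg else TRUE
})

#' Parameters of the synthetic seasonal-expression generator
#'
#' Holds the full sampling design and noise model of [simulateDataset()]:
#' species, tissues, a four-weekly sampling calendar, per-species replicate
#' counts, the mixture of annual / half-annual / arrhythmic genes, the
#' log2-scale oscillation amplitude, negative-binomial overdispersion, the
#' expected library depth, and the winter-lock phase structure.
#'
#' @export
setClass("SimConfig",
  representation(
    nGenes = "integer",
    fracAnnual = "numeric",
    fracHalfAnnual = "numeric",
    fracArrhythmic = "numeric",
    speciesNames = "character",
    tissues = "character",
    nTimepoints = "integer",
    intervalDays = "integer",
    startDate = "Date",
    replicates = "integer",
    amplitudeLog2 = "numeric",
    dispersion = "numeric",
    depth = "numeric",
    winterLockFraction = "numeric",
    growingPhaseSdMonths = "numeric",
    baselineSdLog = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  fr <- c(object@fracAnnual, object@fracHalfAnnual, object@fracArrhythmic)
  if (any(fr < 0) || any(fr > 1))
    msg <- c(msg, "category fractions must lie in [0, 1]")
  if (abs(sum(fr) - 1) > 1e-8)
    msg <- c(msg, "category fractions must sum to 1")
  if (object@nGenes < 1) msg <- c(msg, "nGenes must be >= 1")
  if (object@nTimepoints < 4) msg <- c(msg, "nTimepoints must be >= 4")
  if (object@intervalDays <= 0) msg <- c(msg, "intervalDays must be > 0")
  if (!all(object@speciesNames %in% names(object@replicates)))
    msg <- c(msg, "replicates must be named for every species")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (object@depth <= 0) msg <- c(msg, "depth must be > 0")
  if (object@winterLockFraction < 0 || object@winterLockFraction > 1)
    msg <- c(msg, "winterLockFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Settings of the rhythmicity scan
#'
#' Mirrors the configuration of a RAIN-style umbrella scan over candidate
#' periods: a sampling interval of one time point, candidate periods
#' \code{centerPeriod +/- periodDelta} (floored at 2 time points and capped
#' at one less than the series length), a peak-position window
#' \code{peakBorder} expressed as a fraction of the period, independent
#' treatment of the phase groups, adaptive Benjamini-Hochberg adjustment and
#' a q-value threshold below which a gene is called rhythmic.
#'
#' @export
setClass("RhythmScanParams",
  representation(
    deltat = "integer",
    centerPeriod = "integer",
    periodDelta = "integer",
    peakBorder = "numeric",
    method = "character",
    qThreshold = "numeric",
    adjust = "character",
    exactCap = "integer",
    monthDays = "numeric"
  )
)

setValidity("RhythmScanParams", function(object) {
  msg <- character()
  if (object@deltat != 1L)
    msg <- c(msg, "only deltat = 1 (one observation per time point) is supported")
  if (length(object@peakBorder) != 2 ||
      object@peakBorder[1] < 0 || object@peakBorder[2] > 1 ||
      object@peakBorder[1] >= object@peakBorder[2])
    msg <- c(msg, "peakBorder must be an increasing pair within [0, 1]")
  if (!object@method %in% "independent")
    msg <- c(msg, "method must be 'independent'")
  if (object@qThreshold <= 0 || object@qThreshold > 1)
    msg <- c(msg, "qThreshold must lie in (0, 1]")
  if (!object@adjust %in% c("ABH", "BH"))
    msg <- c(msg, "adjust must be 'ABH' or 'BH'")
  if (object@centerPeriod < 2) msg <- c(msg, "centerPeriod must be >= 2")
  if (object@periodDelta < 0) msg <- c(msg, "periodDelta must be >= 0")
  if (length(msg)) msg else TRUE
})
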