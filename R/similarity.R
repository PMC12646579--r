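#' Align two datasets on equal-length sampling windows
#'
#' Matches time point k of window A to time point k of window B (index
#' alignment), the convention for comparing series sampled over different
#' calendar years at the same season-of-year positions. Rows are restricted
#' to the genes common to both matrices.
#'
#' @param matA,matB normalized matrices (genes x time points) with gene IDs
#'   as rownames.
#' @param windowA,windowB integer column indices of equal length.
#' @return list with aligned matrices \code{A} and \code{B}.
#' @export
alignWindows <- function(matA, matB,
                         windowA = seq_len(ncol(matA)),
                         windowB = seq_len(ncol(matB))) {
  if (length(windowA) != length(windowB))
    stop("windows must contain the same number of time points")
  if (any(windowA < 1 | windowA > ncol(matA)) ||
      any(windowB < 1 | windowB > ncol(matB)))
    stop("window outside the data range")
  genes <- intersect(rownames(matA), rownames(matB))
  if (!length(genes)) stop("no common genes")
  list(A = matA[genes, windowA, drop = FALSE],
       B = matB[genes, windowB, drop = FALSE])
}

#' Per-gene cross-species correlation and mean absolute difference
#'
#' Pearson r and mean absolute difference between the two aligned series of
#' every gene, both computed on the normalized log scale. Genes with a
#' constant series in either species have undefined r and are flagged, not
#' dropped.
#'
#' @param aligned output of [alignWindows()].
#' @return data.frame: \code{gene_id}, \code{r}, \code{mad}, \code{n},
#'   \code{constant}.
#' @export
perGeneCorrelation <- function(aligned) {
  A <- aligned$A; B <- aligned$B
  n <- ncol(A)
  if (n < 3) stop("need at least 3 matched time points")
  constant <- apply(A, 1, stats::sd) == 0 | apply(B, 1, stats::sd) == 0
  r <- rep(NA_real_, nrow(A))
  ok <- !constant
  if (any(ok)) {
    ac <- A[ok, , drop = FALSE] - rowMeans(A[ok, , drop = FALSE])
    bc <- B[ok, , drop = FALSE] - rowMeans(B[ok, , drop = FALSE])
    r[ok] <- rowSums(ac * bc) /
      sqrt(rowSums(ac * ac) * rowSums(bc * bc))
  }
  data.frame(gene_id = rownames(A), r = r,
             mad = rowMeans(abs(A - B)), n = n, constant = constant,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Stratify correlations by rhythmicity category
#'
#' Groups genes into the four seasonal-expression classes --- annual
#' rhythmic peaking in winter, annual rhythmic peaking in the growing
#' season, half-annual rhythmic, and arrhythmic/other --- and reports the
#' median correlation of each class. A gene is annual-winter or
#' annual-growing when annual in both species, classified by the reference
#' species' peak month; half-annual when half-annual in both; everything
#' else is arrhythmic/other.
#'
#' @param corTable output of [perGeneCorrelation()].
#' @param rhythmA,rhythmB rhythm-scan data.frames; A is the reference.
#' @param winterWindow months treated as winter.
#' @return list with \code{table} (corTable plus \code{class}) and
#'   \code{medians} (data.frame class, median_r, n).
#' @export
stratifyByRhythm <- function(corTable, rhythmA, rhythmB,
                             winterWindow = c(12L, 1L, 2L)) {
  catA <- rhythmA$category[match(corTable$gene_id, rhythmA$gene_id)]
  catB <- rhythmB$category[match(corTable$gene_id, rhythmB$gene_id)]
  peakA <- rhythmA$peak_month[match(corTable$gene_id, rhythmA$gene_id)]
  cls <- ifelse(catA == "annual" & catB == "annual",
                ifelse(peakA %in% winterWindow, "annual-winter",
                       "annual-growing"),
                ifelse(catA == "half-annual" & catB == "half-annual",
                       "half-annual", "arrhythmic"))
  cls[is.na(cls)] <- "arrhythmic"
  tab <- cbind(corTable, class = cls, category_a = catA, category_b = catB)
  med <- do.call(rbind, lapply(split(tab, tab$class), function(s) {
    r <- s$r[!is.na(s$r)]
    data.frame(class = s$class[1],
               median_r = if (length(r)) stats::median(r) else NA_real_,
               n = nrow(s))
  }))
  rownames(med) <- NULL
  list(table = tab, medians = med)
}

#' Select genes with extreme mean correlation
#'
#' Top set: mean r at or above the (1 - frac) quantile; bottom set: at or
#' below the frac quantile; all tied genes are included.
#'
#' @param meanR named numeric vector of per-gene mean correlations.
#' @param frac tail fraction in (0, 0.5].
#' @return list with \code{top} and \code{bottom} gene ID vectors.
#' @export
selectExtremes <- function(meanR, frac = 0.05) {
  meanR <- meanR[!is.na(meanR)]
  if (!length(meanR)) stop("empty correlation table")
  if (frac <= 0 || frac > 0.5) stop("frac must lie in (0, 0.5]")
  hi <- stats::quantile(meanR, 1 - frac, names = FALSE)
  lo <- stats::quantile(meanR, frac, names = FALSE)
  list(top = names(meanR)[meanR >= hi], bottom = names(meanR)[meanR <= lo])
}
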