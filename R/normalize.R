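#' Reads per kilobase (RPK)
#'
#' Divides each gene's counts by its length in kilobases:
#' \code{rpk[g, s] = count[g, s] / (length_bp[g] / 1000)}. RPK is the unit of
#' the low-expression filter and the input to GeTMM normalization.
#'
#' @param dataset a \linkS4class{PhenologyExperiment}, or a count matrix if
#'   \code{lengths} is supplied.
#' @param lengths gene lengths in bp (only when \code{dataset} is a matrix).
#' @return numeric matrix of RPK values with the dimensions of the counts.
#' @export
computeRPK <- function(dataset, lengths = NULL) {
  if (methods::is(dataset, "PhenologyExperiment")) {
    cnt <- SummarizedExperiment::assay(dataset, "counts")
    lengths <- geneLengths(dataset)
  } else {
    cnt <- as.matrix(dataset)
    if (is.null(lengths)) stop("lengths required for a plain matrix")
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("gene lengths must be positive")
  cnt / (lengths / 1000)
}

#' Filter genes with low per-species expression
#'
#' A gene is dropped when its mean RPK over one species' samples falls
#' strictly below \code{threshold} in any species under analysis; genes at
#' exactly the threshold are kept.
#'
#' @param rpk RPK matrix from [computeRPK()].
#' @param species character vector assigning each column to a species.
#' @param threshold mean-RPK cutoff (default 1).
#' @return list with \code{keep} (retained gene IDs), \code{drop} (removed
#'   gene IDs) and \code{report} (gene-by-species matrix of mean RPK).
#' @export
filterLowExpression <- function(rpk, species, threshold = 1) {
  species <- as.character(species)
  if (length(species) != ncol(rpk))
    stop("species must assign every sample column")
  groups <- split(seq_len(ncol(rpk)), species)
  if (any(lengths(groups) == 0)) stop("empty species group")
  report <- vapply(groups, function(idx)
    rowMeans(rpk[, idx, drop = FALSE]), numeric(nrow(rpk)))
  low <- apply(report < threshold, 1, any)
  list(keep = rownames(rpk)[!low], drop = rownames(rpk)[low], report = report)
}

#' GeTMM normalization
#'
#' Gene-length-corrected trimmed mean of M-values: the canonical TMM scaling
#' factors are computed on the RPK matrix (reference column chosen by the
#' upper-quartile rule; M- and A-values from genes expressed in both samples;
#' double trimming of \code{trimM} on M and \code{trimA} on A; inverse
#' asymptotic-variance weighting), then each column is scaled to per-million:
#' \code{GeTMM[g, s] = RPK[g, s] / (sum(RPK[, s]) * factor_s) * 1e6}.
#' The TMM step is delegated to \code{edgeR::calcNormFactors}.
#'
#' @param rpk RPK matrix (use [computeRPK()] first), at least two columns.
#' @param trimM,trimA trim fractions for M- and A-values (defaults 0.30 and
#'   0.05, the canonical TMM settings).
#' @return list with \code{getmm} (normalized matrix), \code{factors}
#'   (per-sample TMM factors) and \code{libSize} (per-sample total RPK).
#' @export
getmmNormalize <- function(rpk, trimM = 0.30, trimA = 0.05) {
  rpk <- as.matrix(rpk)
  if (ncol(rpk) < 2) stop("GeTMM requires at least two samples")
  libSize <- colSums(rpk)
  if (any(libSize <= 0)) stop("sample with zero total RPK")
  factors <- edgeR::calcNormFactors(rpk, lib.size = libSize, method = "TMM",
                                    logratioTrim = trimM, sumTrim = trimA)
  getmm <- sweep(rpk, 2, libSize * factors, "/") * 1e6
  list(getmm = getmm, factors = stats::setNames(factors, colnames(rpk)),
       libSize = libSize)
}

#' Average replicates and log-transform
#'
#' Collapses biological replicates by taking the mean GeTMM within each
#' (species, tissue, date) group, then applies \code{log2(mean + 1)} --- the
#' mean is taken before the log.
#'
#' @param getmm GeTMM matrix (genes x samples).
#' @param meta data.frame/DataFrame with \code{species}, \code{tissue},
#'   \code{date} for each column of \code{getmm}.
#' @return a \code{SummarizedExperiment} with assay \code{log2getmm}, one
#'   column per (species, tissue, date).
#' @export
logAverage <- function(getmm, meta) {
  meta <- as.data.frame(meta)
  if (nrow(meta) != ncol(getmm))
    stop("meta must describe every column of getmm")
  key <- paste(meta$species, meta$tissue, meta$date, sep = "|")
  groups <- split(seq_len(ncol(getmm)), key)
  if (any(lengths(groups) == 0)) stop("empty replicate group")
  avg <- vapply(groups, function(idx)
    rowMeans(getmm[, idx, drop = FALSE]), numeric(nrow(getmm)))
  if (is.null(dim(avg)))
    avg <- matrix(avg, nrow = nrow(getmm), ncol = length(groups),
                  dimnames = list(rownames(getmm), names(groups)))
  first <- vapply(groups, `[`, integer(1), 1)
  ord <- order(meta$species[first], meta$tissue[first], meta$date[first])
  avg <- avg[, ord, drop = FALSE]
  first <- first[ord]
  cd <- S4Vectors::DataFrame(species = meta$species[first],
                             tissue = meta$tissue[first],
                             date = as.Date(meta$date[first]))
  colnames(avg) <- paste(cd$species, cd$tissue,
                         format(cd$date, "%Y%m%d"), sep = "_")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2getmm = log2(avg + 1)), colData = cd)
}

#' Seasonal variability ratio
#'
#' Computes, on the normalized log scale, each gene's coefficient of
#' variation over its series (\code{sigma_i / mu_i}), the genome-wide
#' coefficient of variation of the pooled value distribution
#' (\code{sigma_g / mu_g}), and their ratio
#' \code{R = (sigma_g / mu_g) / mean_i(sigma_i / mu_i)} --- the factor by
#' which between-gene variation exceeds within-gene seasonal variation.
#' Genes with zero mean are flagged and excluded from the per-gene average;
#' \code{R} is \code{NA} (flagged) when the per-gene average CV is zero.
#'
#' @param mat normalized matrix (genes x time points), at least two columns.
#' @return list with \code{perGene} (data.frame: gene, mean, sd, cv, flag),
#'   \code{cvGenome}, \code{meanCvGene} and \code{ratio}.
#' @export
variabilityRatio <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least two columns")
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  flagged <- mu == 0
  cv <- ifelse(flagged, NA_real_, sdv / mu)
  cvGenome <- stats::sd(as.vector(mat)) / mean(mat)
  meanCv <- mean(cv[!flagged])
  ratio <- if (!length(cv[!flagged]) || meanCv == 0) NA_real_
           else cvGenome / meanCv
  list(perGene = data.frame(gene_id = rownames(mat), mean = mu, sd = sdv,
                            cv = cv, flagged = flagged,
                            stringsAsFactors = FALSE),
       cvGenome = cvGenome, meanCvGene = meanCv, ratio = ratio)
}
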