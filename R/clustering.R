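#' Row-wise z-scaling
#'
#' Centers every row to mean 0 and scales to standard deviation 1 (sample
#' SD, n - 1). Constant rows are mapped to all-zeros and flagged in the
#' \code{"constant"} attribute.
#'
#' @param mat numeric matrix with at least 2 columns.
#' @return scaled matrix with attribute \code{constant}.
#' @export
zscoreRows <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 columns")
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  constant <- sdv == 0
  out <- (mat - mu) / ifelse(constant, 1, sdv)
  out[constant, ] <- 0
  attr(out, "constant") <- constant
  out
}

#' Within-cluster sum of squares along a dendrogram cut
#'
#' @param mat items x features matrix.
#' @param tree an \code{hclust} object on the rows of \code{mat}.
#' @param kMax largest cluster number evaluated.
#' @return numeric vector WSS(k) for k = 1..kMax.
#' @export
wssCurve <- function(mat, tree, kMax) {
  vapply(seq_len(kMax), function(k) {
    labels <- stats::cutree(tree, k = k)
    sum(vapply(split(seq_len(nrow(mat)), labels), function(idx) {
      sub <- mat[idx, , drop = FALSE]
      sum(sweep(sub, 2, colMeans(sub))^2)
    }, numeric(1)))
  }, numeric(1))
}

#' Geometric elbow of a WSS curve
#'
#' The cluster number maximizing the perpendicular distance from the chord
#' joining (1, WSS(1)) and (kMax, WSS(kMax)). A flat or strictly linear
#' curve has no elbow and returns k = 1 with attribute
#' \code{"no_elbow" = TRUE}.
#'
#' @param wss WSS values for k = 1..length(wss) (length >= 3).
#' @return chosen k.
#' @export
elbowK <- function(wss) {
  kMax <- length(wss)
  if (kMax < 3) stop("curve must have length >= 3")
  x <- seq_len(kMax)
  x1 <- 1; y1 <- wss[1]; x2 <- kMax; y2 <- wss[kMax]
  denom <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  d <- abs((y2 - y1) * x - (x2 - x1) * wss + x2 * y1 - y2 * x1) / denom
  if (max(d) < 1e-9 * max(1, abs(y1))) {
    out <- 1L
    attr(out, "no_elbow") <- TRUE
    return(out)
  }
  which.max(d)
}

#' Ward hierarchical clustering with WSS elbow selection
#'
#' Agglomerative clustering with Ward's minimum-variance criterion
#' (\code{ward.D2}, squared-Euclidean objective) on Euclidean distances,
#' the WSS curve for k = 1..kMax, and the elbow-selected cut.
#'
#' @param mat numeric matrix; rows or columns are clustered according to
#'   \code{axis}.
#' @param axis \code{"rows"} or \code{"cols"}.
#' @param kMax largest k scanned for the WSS elbow (default 15, capped at
#'   the item count).
#' @return list with \code{tree} (hclust), \code{wss}, \code{k} and
#'   \code{labels}.
#' @export
wardCluster <- function(mat, axis = c("rows", "cols"), kMax = 15) {
  axis <- match.arg(axis)
  items <- if (axis == "rows") as.matrix(mat) else t(as.matrix(mat))
  if (nrow(items) < 2) stop("need at least 2 items")
  kMax <- min(kMax, nrow(items))
  tree <- stats::hclust(stats::dist(items), method = "ward.D2")
  wss <- wssCurve(items, tree, kMax)
  k <- if (kMax >= 3) as.integer(elbowK(wss)) else 1L
  list(tree = tree, wss = wss, k = k,
       labels = stats::cutree(tree, k = k))
}

#' Principal component analysis of expression profiles
#'
#' Thin wrapper around \code{stats::prcomp} (columns centered internally,
#' not scaled) returning scores, loadings and the fraction of variance per
#' component.
#'
#' @param mat items x features matrix.
#' @param nComp number of components to keep (default all).
#' @return list with \code{scores}, \code{loadings}, \code{varFrac}.
#' @export
pcaProfiles <- function(mat, nComp = NULL) {
  mat <- as.matrix(mat)
  full <- min(dim(mat) - c(1, 0))
  if (is.null(nComp)) nComp <- full
  if (nComp > min(dim(mat))) stop("nComp exceeds the matrix dimensions")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  keep <- seq_len(min(nComp, ncol(pc$x)))
  varFrac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, keep, drop = FALSE],
       loadings = pc$rotation[, keep, drop = FALSE],
       varFrac = varFrac[seq_len(min(nComp, length(varFrac)))],
       varFracAll = varFrac)
}
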