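#' NG86 synonymous and nonsynonymous site counts of one codon
#'
#' At each of the three positions the codon carries one site, split by the
#' fraction of its non-stop single-base mutants that are synonymous
#' (mutations to stop codons are excluded from the denominator). Returns
#' \code{c(s, n)} with \code{s + n = 3}.
#'
#' @param codon a 3-letter codon (case-insensitive).
#' @return named numeric vector \code{c(s = ..., n = ...)}.
#' @export
ng86Sites <- function(codon) {
  codon <- toupper(codon)
  tab <- codonTables()
  if (!codon %in% tab$sense)
    stop("not a sense codon: ", codon)
  s <- tab$synSites[[codon]]
  c(s = s, n = 3 - s)
}

# classify each minimal mutational pathway between two codons differing at
# `diffPos`; returns average (syn, nonsyn) step counts over pathways that
# avoid stop codons (all pathways if every one passes through a stop)
pathwayCounts <- function(a, b, tab) {
  diffPos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  nd <- length(diffPos)
  if (nd == 0) return(c(syn = 0, nonsyn = 0))
  orders <- if (nd == 1) list(diffPos)
            else if (nd == 2) list(diffPos, rev(diffPos))
            else {
    prm <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    lapply(prm, function(o) diffPos[o])
  }
  bChars <- strsplit(b, "")[[1]]
  res <- matrix(NA_real_, length(orders), 2)
  valid <- logical(length(orders))
  for (oi in seq_along(orders)) {
    cur <- a
    sSteps <- 0; nSteps <- 0; ok <- TRUE
    for (pos in orders[[oi]]) {
      nxtChars <- strsplit(cur, "")[[1]]
      nxtChars[pos] <- bChars[pos]
      nxt <- paste(nxtChars, collapse = "")
      if (tab$aa[[nxt]] == "*") { ok <- FALSE; break }
      if (tab$aa[[nxt]] == tab$aa[[cur]]) sSteps <- sSteps + 1
      else nSteps <- nSteps + 1
      cur <- nxt
    }
    valid[oi] <- ok
    res[oi, ] <- c(sSteps, nSteps)
  }
  use <- if (any(valid)) valid else rep(TRUE, length(orders))
  # pathways cut short at a stop codon are only used as a last resort; in
  # that case score them by re-walking without the stop exclusion
  if (!any(valid)) {
    for (oi in seq_along(orders)) {
      cur <- a; sSteps <- 0; nSteps <- 0
      for (pos in orders[[oi]]) {
        nxtChars <- strsplit(cur, "")[[1]]
        nxtChars[pos] <- bChars[pos]
        nxt <- paste(nxtChars, collapse = "")
        if (tab$aa[[nxt]] != "*" && tab$aa[[nxt]] == tab$aa[[cur]])
          sSteps <- sSteps + 1
        else nSteps <- nSteps + 1
        cur <- nxt
      }
      res[oi, ] <- c(sSteps, nSteps)
    }
  }
  c(syn = mean(res[use, 1]), nonsyn = mean(res[use, 2]))
}

#' Pairwise NG86 divergence with Jukes-Cantor correction
#'
#' Counting estimator of dN and dS for a codon-aligned sequence pair: site
#' counts are averaged over the two sequences, multi-difference codons are
#' resolved by averaging over all minimal mutational pathways (pathways
#' through stop codons excluded), proportions \code{pS = sd/S},
#' \code{pN = nd/N} are Jukes-Cantor corrected via
#' \code{d = -(3/4) log(1 - 4p/3)}, and \code{omega = dN/dS}. Codons
#' containing gaps, ambiguous bases or stop codons in either sequence are
#' masked and counted. A proportion at or above 3/4 leaves the corrected
#' distance undefined and flags the record as saturated.
#'
#' @param seqA,seqB character strings or \code{DNAString}s of equal length,
#'   a multiple of 3.
#' @return one-row data.frame with S, N, sd, nd, pS, pN, dS, dN, omega,
#'   codons used/masked and the \code{saturated} flag.
#' @export
ng86Dnds <- function(seqA, seqB) {
  a <- toupper(as.character(seqA))
  b <- toupper(as.character(seqB))
  if (nchar(a) != nchar(b)) stop("sequences must be equal length")
  if (nchar(a) %% 3 != 0) stop("length must be a multiple of 3")
  tab <- codonTables()
  starts <- seq(1, nchar(a), by = 3)
  codA <- substring(a, starts, starts + 2)
  codB <- substring(b, starts, starts + 2)
  ok <- codA %in% tab$sense & codB %in% tab$sense
  nMasked <- sum(!ok)
  codA <- codA[ok]; codB <- codB[ok]
  if (!length(codA)) stop("no scorable codons")
  S <- (sum(tab$synSites[codA]) + sum(tab$synSites[codB])) / 2
  N <- 3 * length(codA) - S
  sd_ <- 0; nd_ <- 0
  for (i in which(codA != codB)) {
    pc <- pathwayCounts(codA[i], codB[i], tab)
    sd_ <- sd_ + pc[["syn"]]
    nd_ <- nd_ + pc[["nonsyn"]]
  }
  pS <- sd_ / S
  pN <- nd_ / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  saturated <- pS >= 0.75 || pN >= 0.75
  omega <- if (is.na(dS) || is.na(dN)) NA_real_
           else if (dS > 0) dN / dS
           else if (dN > 0) Inf
           else NA_real_
  data.frame(S = S, N = N, sd = sd_, nd = nd_, pS = pS, pN = pN,
             dS = dS, dN = dN, omega = omega,
             n_codons = length(codA), n_masked = nMasked,
             saturated = saturated)
}

#' NG86 divergence for a set of ortholog pairs
#'
#' Applies [ng86Dnds()] to every pair in a \code{DNAStringSet} whose names
#' follow the \code{"<pairID>|<species>"} convention (two records per
#' pair ID).
#'
#' @param pairs a \code{Biostrings::DNAStringSet} or path to a FASTA file.
#' @return data.frame with one row per pair (column \code{pair_id} plus the
#'   [ng86Dnds()] fields).
#' @export
ng86Pairs <- function(pairs) {
  if (is.character(pairs)) pairs <- Biostrings::readDNAStringSet(pairs)
  ids <- sub("\\|.*$", "", names(pairs))
  rows <- lapply(unique(ids), function(id) {
    idx <- which(ids == id)
    if (length(idx) != 2)
      stop("pair ", id, " does not have exactly 2 sequences")
    cbind(pair_id = id,
          ng86Dnds(pairs[[idx[1]]], pairs[[idx[2]]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter divergence records
#'
#' Removes records with \code{omega >= maxOmega}, \code{dS > maxDs},
#' \code{dS < minDs} or \code{dN < minDn} (saturated or undefined rates are
#' also removed) and reports the count removed by each rule.
#'
#' @param records data.frame with \code{dN}, \code{dS}, \code{omega}.
#' @param maxOmega,maxDs,minDs,minDn filter thresholds (defaults 99, 10,
#'   0.001, 0.0003).
#' @return list with \code{kept}, \code{removed} and \code{report} (counts
#'   per rule; a record may violate several).
#' @export
filterDivergence <- function(records, maxOmega = 99, maxDs = 10,
                             minDs = 0.001, minDn = 3e-4) {
  undef <- is.na(records$dS) | is.na(records$dN)
  byOmega <- !undef & !is.na(records$omega) & records$omega >= maxOmega
  dsHigh <- !undef & records$dS > maxDs
  dsLow <- !undef & records$dS < minDs
  dnLow <- !undef & records$dN < minDn
  drop <- undef | byOmega | dsHigh | dsLow | dnLow
  list(kept = records[!drop, , drop = FALSE],
       removed = records[drop, , drop = FALSE],
       report = c(undefined_or_saturated = sum(undef),
                  omega_ge_max = sum(byOmega),
                  ds_gt_max = sum(dsHigh),
                  ds_lt_min = sum(dsLow),
                  dn_lt_min = sum(dnLow),
                  total_removed = sum(drop)))
}

#' Regress log2 evolutionary rates on a predictor
#'
#' Ordinary least squares of \code{log2(rate)} on a predictor column
#' (typically the circular peak-month difference or the mean expression
#' level), with a t-test on the slope. Records with non-positive or
#' non-finite rates are excluded from the log transform and counted.
#'
#' @param records data.frame holding the rate and predictor columns.
#' @param predictor name of the predictor column.
#' @param response name of the rate column (\code{"omega"}, \code{"dN"} or
#'   \code{"dS"}).
#' @param conf confidence level for the slope interval.
#' @return one-row data.frame: response, predictor, beta, se, t, p, CI
#'   bounds, n used and n excluded.
#' @export
regressRates <- function(records, predictor, response = "omega",
                         conf = 0.95) {
  if (!predictor %in% names(records)) stop("unknown predictor: ", predictor)
  if (!response %in% names(records)) stop("unknown response: ", response)
  y <- records[[response]]
  x <- records[[predictor]]
  use <- is.finite(y) & y > 0 & is.finite(x)
  nExcluded <- sum(!use)
  y <- log2(y[use]); x <- x[use]
  if (length(y) < 3) stop("need at least 3 usable records")
  if (stats::sd(x) == 0) stop("predictor is constant")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, "x", level = conf)
  data.frame(response = response, predictor = predictor,
             beta = sm["x", "Estimate"], se = sm["x", "Std. Error"],
             t = sm["x", "t value"], p = sm["x", "Pr(>|t|)"],
             ci_lo = ci[1], ci_hi = ci[2],
             n = length(y), n_excluded = nExcluded,
             stringsAsFactors = FALSE)
}
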