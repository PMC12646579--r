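#' Circular difference between two calendar months
#'
#' Distance on the 12-month ring: \code{min(|a - b|, 12 - |a - b|)},
#' symmetric, in 0..6.
#'
#' @param a,b month numbers in 1..12 (vectorized).
#' @return integer vector of circular differences.
#' @export
circularMonthDiff <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (any(a < 1 | a > 12 | b < 1 | b > 12, na.rm = TRUE))
    stop("months must lie in 1..12")
  d <- abs(a - b)
  pmin(d, 12L - d)
}

#' Peak-month comparison matrix for a species pair
#'
#' Restricted to genes with annual periodicity in both species, tabulates
#' gene counts over the 12 x 12 grid of (peak month in A, peak month in B),
#' with the per-cell mean Pearson correlation when a correlation table is
#' supplied, and flags cells and genes whose correlation falls below
#' \code{divergentR}.
#'
#' @param rhythmA,rhythmB rhythm-scan result data.frames (from
#'   [rhythmScan()]) for the two species.
#' @param correlations optional data.frame with \code{gene_id} and \code{r}.
#' @param divergentR flagging threshold on r (default -0.3).
#' @return list with \code{counts} (12 x 12), \code{meanR}, \code{divergent}
#'   (logical 12 x 12), \code{genes} (per-gene table) and the pair size.
#' @export
peakComparisonMatrix <- function(rhythmA, rhythmB, correlations = NULL,
                                 divergentR = -0.3) {
  aAnn <- rhythmA[rhythmA$category == "annual", c("gene_id", "peak_month")]
  bAnn <- rhythmB[rhythmB$category == "annual", c("gene_id", "peak_month")]
  shared <- merge(aAnn, bAnn, by = "gene_id", suffixes = c("_a", "_b"))
  if (nrow(shared) == 0) stop("no gene is annual-rhythmic in both species")
  if (!is.null(correlations))
    shared$r <- correlations$r[match(shared$gene_id, correlations$gene_id)]
  counts <- matrix(0L, 12, 12, dimnames = list(monthA = 1:12, monthB = 1:12))
  meanR <- matrix(NA_real_, 12, 12, dimnames = dimnames(counts))
  tab <- table(factor(shared$peak_month_a, levels = 1:12),
               factor(shared$peak_month_b, levels = 1:12))
  counts[] <- as.integer(tab)
  if (!is.null(correlations)) {
    agg <- stats::aggregate(r ~ peak_month_a + peak_month_b, data = shared,
                            FUN = mean, na.rm = TRUE)
    meanR[cbind(agg$peak_month_a, agg$peak_month_b)] <- agg$r
  }
  divergent <- !is.na(meanR) & meanR < divergentR
  if (!is.null(correlations))
    shared$divergent <- !is.na(shared$r) & shared$r < divergentR
  list(counts = counts, meanR = meanR, divergent = divergent,
       genes = shared, nGenes = nrow(shared))
}

#' Molecular phenology divergence index D
#'
#' For reference species A and month \code{t}, the proportion of genes
#' peaking in month \code{t} in A whose peak month in species B differs by
#' at least \code{threshold} months on the circular scale:
#' \code{D(t) = #\{phi_A = t, delta_phi >= threshold\} / #\{phi_A = t\}}.
#' Months in which no gene peaks in A have undefined D (\code{NA}), not 0.
#' D is directional; swap the arguments for the reverse direction.
#'
#' @param peaksA,peaksB named integer vectors of peak months over the same
#'   gene set (annual-rhythmic in both species); names are gene IDs.
#' @param months months to evaluate (default all 12).
#' @param threshold minimum circular peak-month difference counted as
#'   divergent (default 2).
#' @return data.frame with \code{month}, \code{D}, \code{n_divergent},
#'   \code{n_total}.
#' @export
divergenceIndex <- function(peaksA, peaksB, months = 1:12, threshold = 2) {
  if (length(peaksA) != length(peaksB))
    stop("peak vectors must cover the same genes")
  if (!is.null(names(peaksA)) && !is.null(names(peaksB))) {
    peaksB <- peaksB[names(peaksA)]
    if (anyNA(names(peaksB))) stop("gene sets differ between species")
  }
  dphi <- circularMonthDiff(peaksA, peaksB)
  out <- data.frame(month = as.integer(months), D = NA_real_,
                    n_divergent = 0L, n_total = 0L)
  for (i in seq_along(months)) {
    at <- which(peaksA == months[i])
    out$n_total[i] <- length(at)
    out$n_divergent[i] <- sum(dphi[at] >= threshold)
    if (length(at)) out$D[i] <- out$n_divergent[i] / out$n_total[i]
  }
  out
}

#' Monthly divergence profile over all species pairs
#'
#' Computes [divergenceIndex()] for every ordered species pair (reference
#' first) on the genes annual-rhythmic in both, labels pairs as intra-genus
#' or inter-genera, and attaches per-month summaries.
#'
#' @param rhythmList named list of rhythm-scan data.frames, one per species.
#' @param genus named character vector mapping species to genus; defaults to
#'   the first character of each species name.
#' @param threshold divergence threshold on the circular month difference.
#' @return data.frame in long format: \code{pair}, \code{ref},
#'   \code{other}, \code{grouping}, \code{month}, \code{D},
#'   \code{n_divergent}, \code{n_total}.
#' @export
monthlyProfile <- function(rhythmList, genus = NULL, threshold = 2) {
  spp <- names(rhythmList)
  if (length(spp) < 2) stop("need at least 2 species")
  if (is.null(genus))
    genus <- stats::setNames(substr(spp, 1, 1), spp)
  rows <- list()
  for (a in spp) for (b in spp) {
    if (a == b) next
    ra <- rhythmList[[a]]; rb <- rhythmList[[b]]
    ga <- ra[ra$category == "annual", ]
    gb <- rb[rb$category == "annual", ]
    common <- intersect(ga$gene_id, gb$gene_id)
    di <- if (length(common)) {
      pa <- stats::setNames(ga$peak_month[match(common, ga$gene_id)], common)
      pb <- stats::setNames(gb$peak_month[match(common, gb$gene_id)], common)
      divergenceIndex(pa, pb, threshold = threshold)
    } else {
      data.frame(month = 1:12, D = NA_real_, n_divergent = 0L, n_total = 0L)
    }
    di$pair <- paste(a, b, sep = "-")
    di$ref <- a; di$other <- b
    di$grouping <- if (genus[[a]] == genus[[b]]) "intra-genus" else "inter-genera"
    rows[[length(rows) + 1L]] <- di
  }
  out <- do.call(rbind, rows)
  out[, c("pair", "ref", "other", "grouping", "month", "D",
          "n_divergent", "n_total")]
}

#' Summarize a divergence profile by month
#'
#' Mean and SD of D per month, overall and split by intra-genus versus
#' inter-genera pairs; undefined D values are excluded, not imputed.
#'
#' @param profile output of [monthlyProfile()].
#' @return data.frame with \code{month}, \code{grouping} (including
#'   \code{"all"}), \code{mean_D}, \code{sd_D}, \code{n_pairs}.
#' @export
summarizeProfile <- function(profile) {
  blocks <- c("all", unique(profile$grouping))
  rows <- list()
  for (g in blocks) {
    sub <- if (g == "all") profile else profile[profile$grouping == g, ]
    for (m in sort(unique(sub$month))) {
      d <- sub$D[sub$month == m]
      d <- d[!is.na(d)]
      rows[[length(rows) + 1L]] <- data.frame(
        month = m, grouping = g,
        mean_D = if (length(d)) mean(d) else NA_real_,
        sd_D = if (length(d) > 1) stats::sd(d) else NA_real_,
        n_pairs = length(d))
    }
  }
  do.call(rbind, rows)
}

#' Compare divergence across months (Friedman + Nemenyi letters)
#'
#' Treats species pairs as blocks and months as treatments, runs a Friedman
#' rank test over the months with D defined in every block, then all
#' pairwise Nemenyi comparisons (studentized-range reference distribution)
#' and a compact letter display at level \code{alpha}: months sharing no
#' letter differ significantly.
#'
#' @param profile output of [monthlyProfile()].
#' @param alpha significance level for the letter display.
#' @return list with \code{friedman_p}, \code{p_matrix} (pairwise Nemenyi
#'   p-values), \code{letters} (named by month), \code{months} used and the
#'   block count.
#' @export
compareMonths <- function(profile, alpha = 0.05) {
  wide <- stats::reshape(
    profile[, c("pair", "month", "D")], idvar = "pair",
    timevar = "month", direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  months <- as.integer(sub("^D\\.", "", colnames(mat)))
  keep <- colSums(is.na(mat)) == 0
  mat <- mat[, keep, drop = FALSE]
  months <- months[keep]
  if (ncol(mat) < 3) stop("need at least 3 months with D defined in every block")
  if (nrow(mat) < 2) stop("need at least 2 complete blocks")
  fr <- stats::friedman.test(mat)
  frP <- fr$p.value
  if (is.nan(frP)) frP <- 1   # zero rank variance: all months identical
  k <- ncol(mat); nb <- nrow(mat)
  ranks <- t(apply(mat, 1, rank))
  meanRank <- colMeans(ranks)
  pm <- matrix(1, k, k, dimnames = list(months, months))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    q <- abs(meanRank[i] - meanRank[j]) / sqrt(k * (k + 1) / (12 * nb))
    pv <- stats::ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
    pm[i, j] <- pm[j, i] <- pv
  }
  letters <- cldLetters(pm < alpha, order(meanRank))
  names(letters) <- months
  list(friedman_p = frP, p_matrix = pm, letters = letters,
       mean_rank = stats::setNames(meanRank, months),
       months = months, n_blocks = nb)
}

# insert-and-absorb compact letter display from a significant-difference
# matrix; `ord` orders treatments (e.g. by mean rank) for letter assignment
cldLetters <- function(sig, ord = seq_len(ncol(sig))) {
  k <- ncol(sig)
  groups <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      if (i %in% g && j %in% g) {
        groups[[gi]] <- setdiff(g, i)
        groups[[length(groups) + 1L]] <- setdiff(g, j)
      }
    }
    # absorb groups contained in another
    drop <- rep(FALSE, length(groups))
    for (a in seq_along(groups)) for (b in seq_along(groups)) {
      if (a != b && !drop[a] && !drop[b] &&
          all(groups[[a]] %in% groups[[b]]))
        drop[a] <- TRUE
    }
    groups <- groups[!drop]
  }
  # order groups by the smallest ordered member for stable letters
  firstPos <- vapply(groups, function(g) min(match(g, ord)), numeric(1))
  groups <- groups[order(firstPos)]
  out <- character(k)
  for (gi in seq_along(groups))
    for (m in groups[[gi]])
      out[m] <- paste0(out[m], letters[gi])
  out
}

#' Fraction of peaks falling in a month window
#'
#' @param peaks integer vector of peak months (1..12).
#' @param window months counted as the target season (default
#'   December--February).
#' @return fraction of peaks inside the window.
#' @export
winterShare <- function(peaks, window = c(12L, 1L, 2L)) {
  peaks <- peaks[!is.na(peaks)]
  if (!length(peaks)) stop("empty peak set")
  if (any(peaks < 1 | peaks > 12)) stop("months must lie in 1..12")
  mean(peaks %in% window)
}
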