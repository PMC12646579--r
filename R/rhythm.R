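#' @include AllClasses.R
NULL

#' Create rhythm-scan settings
#'
#' Defaults reproduce a four-weekly two-year design scanned for seasonal
#' periodicity: candidate periods 12 +/- 11 time points (floored at 2 and
#' capped at one less than the series length), peaks allowed anywhere within
#' the period, independent phase groups, adaptive Benjamini-Hochberg
#' q-values and a rhythmicity call at q < 0.01.
#'
#' @param deltat sampling interval in time points (only 1 supported).
#' @param centerPeriod,periodDelta candidate periods
#'   \code{centerPeriod +/- periodDelta} in time points.
#' @param peakBorder length-2 fraction interval restricting peak positions
#'   within the period.
#' @param method phase-group treatment; \code{"independent"}.
#' @param qThreshold q-value below which a gene is called rhythmic.
#' @param adjust multiple-testing adjustment, \code{"ABH"} or \code{"BH"}.
#' @param exactCap largest total series length for which the exact null is
#'   used; longer series fall back to a normal approximation with
#'   continuity correction.
#' @param monthDays days per month used for period conversion
#'   (365.25 / 12).
#' @return a validated \linkS4class{RhythmScanParams}.
#' @export
rhythmScanParams <- function(deltat = 1L, centerPeriod = 12L,
                             periodDelta = 11L, peakBorder = c(0, 1),
                             method = "independent", qThreshold = 0.01,
                             adjust = "ABH", exactCap = 40L,
                             monthDays = 365.25 / 12) {
  methods::new("RhythmScanParams",
    deltat = as.integer(deltat), centerPeriod = as.integer(centerPeriod),
    periodDelta = as.integer(periodDelta), peakBorder = as.numeric(peakBorder),
    method = method, qThreshold = qThreshold, adjust = adjust,
    exactCap = as.integer(exactCap), monthDays = monthDays)
}

## ---- exact null machinery -------------------------------------------------

.rhythmCache <- new.env(parent = emptyenv())

# Mann-Whitney null pmf of U = #{x in group1 < y in group2}, sizes (m, n).
# Recursion on the largest observation: coming from group1 (probability
# m/(m+n)) it adds 0; from group2 it exceeds all m group1 members and adds m.
mwPmf <- function(m, n) {
  key <- paste0("mw", m, ".", n)
  hit <- .rhythmCache[[key]]
  if (!is.null(hit)) return(hit)
  res <- if (m == 0 || n == 0) 1 else {
    a <- mwPmf(m - 1, n)
    b <- mwPmf(m, n - 1)
    out <- numeric(m * n + 1)
    out[seq_along(a)] <- out[seq_along(a)] + m / (m + n) * a
    out[m + seq_along(b)] <- out[m + seq_along(b)] + n / (m + n) * b
    out
  }
  .rhythmCache[[key]] <- res
  res
}

convolvePmf <- function(a, b) {
  if (length(b) == 1) return(a * b)
  if (length(a) == 1) return(b * a)
  r <- numeric(length(a) + length(b) - 1)
  ib <- seq_along(b) - 1L
  for (i in seq_along(a)) if (a[i] > 0) r[i + ib] <- r[i + ib] + a[i] * b
  r
}

# Mann-Whitney components whose independent convolution gives the exact
# umbrella null: the rise arm's Jonckheere-Terpstra part (groups before the
# peak), the fall arm's (groups after the peak), and one Mann-Whitney term of
# all non-peak observations against the peak group. The arms share the peak
# group in the statistic, but factoring the peak group into the final
# Mann-Whitney term renders the three pieces mutually independent under the
# null (verified by exhaustive enumeration in the tests).
umbrellaNullComponents <- function(sizes, peakK) {
  k <- length(sizes)
  comp <- list()
  if (peakK >= 3)
    for (j in 2:(peakK - 1))
      comp[[length(comp) + 1L]] <- c(sum(sizes[1:(j - 1)]), sizes[j])
  if (k - peakK >= 2)
    for (j in (k - 1):(peakK + 1))
      comp[[length(comp) + 1L]] <- c(sum(sizes[(j + 1):k]), sizes[j])
  comp[[length(comp) + 1L]] <- c(sum(sizes[-peakK]), sizes[peakK])
  comp[vapply(comp, function(cc) all(cc > 0), logical(1))]
}

umbrellaNullPmf <- function(sizes, peakK) {
  pmf <- 1
  for (cc in umbrellaNullComponents(sizes, peakK))
    pmf <- convolvePmf(pmf, mwPmf(cc[1], cc[2]))
  pmf / sum(pmf)
}

umbrellaNullMoments <- function(sizes, peakK) {
  comp <- umbrellaNullComponents(sizes, peakK)
  mu <- sum(vapply(comp, function(cc) cc[1] * cc[2] / 2, numeric(1)))
  v <- sum(vapply(comp, function(cc)
    cc[1] * cc[2] * (cc[1] + cc[2] + 1) / 12, numeric(1)))
  c(mean = mu, var = v)
}

#' Umbrella-alternative rank statistic
#'
#' Assigns observations to phase groups \code{g = ((index - 1) mod periodTp)
#' + 1} and scores the rise-then-fall (umbrella) ordering with a Mack-Wolfe
#' sum of pairwise Mann-Whitney counts: ascending pairs below the peak group
#' and descending pairs above it, ties contributing 0.5. Because a seasonal
#' oscillation is circular in phase, the ordering may be rotated: with
#' \code{rotation = s} the umbrella runs over groups
#' \code{s+1, ..., periodTp, 1, ..., s}, placing the cycle's trough at the
#' rotation boundary.
#'
#' @param x numeric series (NAs dropped, group membership kept by original
#'   index).
#' @param periodTp candidate period in time points.
#' @param peakK peak position within the (rotated) group order,
#'   \code{1 <= peakK <= periodTp}.
#' @param rotation cyclic offset of the group order (0..periodTp-1).
#' @return list with the statistic \code{U}, its maximum \code{Umax}, the
#'   rotated phase-group \code{sizes}, the original label of the peak group
#'   \code{peakGroup} and \code{ties} (whether tied values entered any
#'   counted pair).
#' @export
umbrellaStatistic <- function(x, periodTp, peakK, rotation = 0L) {
  if (peakK < 1 || peakK > periodTp)
    stop("peakK must lie in 1..periodTp")
  idx <- seq_along(x)
  keep <- !is.na(x)
  x <- x[keep]; idx <- idx[keep]
  if (length(x) < periodTp)
    stop("series shorter than candidate period")
  g <- ((idx - 1L) %% periodTp) + 1L
  pos <- ((g - 1L - as.integer(rotation)) %% periodTp) + 1L
  if (length(unique(pos)) < 2) stop("fewer than 2 nonempty phase groups")
  U <- 0; Umax <- 0; ties <- FALSE
  for (s in seq_len(periodTp)) for (d in seq_len(periodTp)) {
    if (!((s < d && d <= peakK) || (s > d && d >= peakK))) next
    xs <- x[pos == s]; xd <- x[pos == d]
    if (!length(xs) || !length(xd)) next
    eq <- sum(outer(xs, xd, "=="))
    if (eq > 0) ties <- TRUE
    U <- U + sum(outer(xs, xd, "<")) + 0.5 * eq
    Umax <- Umax + length(xs) * length(xd)
  }
  list(U = U, Umax = Umax, sizes = tabulate(pos, periodTp), peakK = peakK,
       peakGroup = ((peakK - 1L + as.integer(rotation)) %% periodTp) + 1L,
       ties = ties)
}

#' Exact or approximate null p-value of the umbrella statistic
#'
#' For total sample sizes up to \code{exactCap} the exact null distribution
#' is computed by convolving the independent Mann-Whitney components of the
#' statistic (no-tie null); beyond the cap a normal approximation with
#' continuity correction and the exact mean and variance is used.
#'
#' @param U observed statistic (half-integers from midrank ties are rounded
#'   up to the next achievable value).
#' @param sizes per-group sample sizes (zeros allowed).
#' @param peakK index of the peak group within \code{sizes}.
#' @param exactCap largest total n for the exact path.
#' @return \code{P(U_null >= U)}.
#' @export
exactNullPvalue <- function(U, sizes, peakK, exactCap = 40L) {
  comp <- umbrellaNullComponents(sizes, peakK)
  Umax <- sum(vapply(comp, function(cc) cc[1] * cc[2], numeric(1)))
  if (U < -1e-9 || U > Umax + 1e-9)
    stop("U outside [0, ", Umax, "]")
  n <- sum(sizes)
  if (n <= exactCap) {
    tail <- nullTailFor(comp)
    u0 <- min(as.integer(ceiling(U - 1e-9)), Umax)
    tail[u0 + 1]
  } else {
    mo <- umbrellaNullMoments(sizes, peakK)
    stats::pnorm(U - 0.5, mean = mo["mean"], sd = sqrt(mo["var"]),
                 lower.tail = FALSE)
  }
}

## ---- candidate grid and vectorized scan engine ----------------------------

# all (period, rotation, peak-position) candidates: the rotation places the
# cycle's trough, the peak position within the rotated order sets the rise
# length; peakBorder restricts the allowed peak positions
candidateGrid <- function(n, params) {
  tMin <- max(2L, params@centerPeriod - params@periodDelta)
  tMax <- min(params@centerPeriod + params@periodDelta, n - 1L)
  if (tMax < tMin) stop("series too short for any candidate period")
  b <- params@peakBorder
  rows <- list()
  for (tp in tMin:tMax) for (rot in 0:(tp - 1L)) for (pk in seq_len(tp)) {
    if (pk / tp > b[1] && (pk - 1) / tp < b[2])
      rows[[length(rows) + 1L]] <- c(tp, rot, pk)
  }
  m <- do.call(rbind, rows)
  data.frame(periodTp = m[, 1], rotation = m[, 2], peakK = m[, 3])
}

# exact null tail P(U >= u), cached by the multiset of Mann-Whitney
# components (convolution is order-free, so rotations sharing component
# sizes share one distribution)
nullTailFor <- function(comp) {
  key <- paste0("tail_", paste(vapply(comp, function(cc)
    paste(cc, collapse = "x"), character(1))[order(vapply(comp, paste,
    character(1), collapse = "x"))], collapse = "_"))
  hit <- .rhythmCache[[key]]
  if (!is.null(hit)) return(hit)
  pmf <- 1
  for (cc in comp) pmf <- convolvePmf(pmf, mwPmf(cc[1], cc[2]))
  tail <- rev(cumsum(rev(pmf / sum(pmf))))
  .rhythmCache[[key]] <- tail
  tail
}

# cached per-(n, params) scan tables: deduplicated pair masks and null
# tails; distinct candidates define the Bonferroni count
scanEngine <- function(n, params) {
  key <- paste("scan", n, params@centerPeriod, params@periodDelta,
               paste(params@peakBorder, collapse = "-"), params@exactCap,
               sep = "_")
  hit <- .rhythmCache[[key]]
  if (!is.null(hit)) return(hit)
  cand <- candidateGrid(n, params)
  nc <- nrow(cand)
  Mt <- matrix(0, n * n, nc)
  seqn <- seq_len(n)
  for (ci in seq_len(nc)) {
    tp <- cand$periodTp[ci]
    g <- ((seqn - 1L) %% tp) + 1L
    pos <- ((g - 1L - cand$rotation[ci]) %% tp) + 1L
    pk <- cand$peakK[ci]
    gi <- matrix(pos, n, n)          # rotated position of row index i
    gj <- t(gi)                      # rotated position of column index j
    Mt[, ci] <- as.numeric((gi < gj & gj <= pk) | (gi > gj & gj >= pk))
  }
  dupKey <- apply(Mt, 2, paste, collapse = "")
  keep <- !duplicated(dupKey)
  cand <- cand[keep, , drop = FALSE]
  Mt <- Mt[, keep, drop = FALSE]
  nc <- nrow(cand)
  tails <- vector("list", nc)
  moments <- matrix(NA_real_, nc, 2)
  Umax <- numeric(nc)
  exact <- n <= params@exactCap
  for (ci in seq_len(nc)) {
    tp <- cand$periodTp[ci]
    g <- ((seqn - 1L) %% tp) + 1L
    pos <- ((g - 1L - cand$rotation[ci]) %% tp) + 1L
    sizes <- tabulate(pos, tp)
    comp <- umbrellaNullComponents(sizes, cand$peakK[ci])
    Umax[ci] <- sum(vapply(comp, function(cc) cc[1] * cc[2], numeric(1)))
    if (exact) tails[[ci]] <- nullTailFor(comp)
    else moments[ci, ] <- umbrellaNullMoments(sizes, cand$peakK[ci])
  }
  hit <- list(cand = cand, Mt = Mt, tails = tails, moments = moments,
              Umax = Umax, exact = exact, n = n)
  .rhythmCache[[key]] <- hit
  hit
}

# pairwise comparison expansion: row g of the result holds, column-major over
# (i, j), the value (x_i < x_j) + 0.5 (x_i == x_j) for gene g
pairComparisons <- function(mat) {
  n <- ncol(mat)
  a <- mat[, rep(seq_len(n), times = n), drop = FALSE]
  b <- mat[, rep(seq_len(n), each = n), drop = FALSE]
  (a < b) + 0.5 * (a == b)
}

scanPvalues <- function(mat, engine) {
  U <- pairComparisons(mat) %*% engine$Mt
  p <- matrix(1, nrow(U), ncol(U))
  for (ci in seq_len(ncol(U))) {
    if (engine$exact) {
      u0 <- pmin(as.integer(ceiling(U[, ci] - 1e-9)), engine$Umax[ci])
      p[, ci] <- engine$tails[[ci]][u0 + 1L]
    } else {
      p[, ci] <- stats::pnorm(U[, ci] - 0.5, mean = engine$moments[ci, 1],
                              sd = sqrt(engine$moments[ci, 2]),
                              lower.tail = FALSE)
    }
  }
  list(U = U, p = p)
}

#' Scan one series for rhythmicity
#'
#' Evaluates every candidate (period, peak) combination, computes the exact
#' (or normal-approximate) umbrella p-value of each, and returns the best
#' candidate with a Bonferroni correction over the number of candidates.
#' Missing values are dropped while group membership is kept by the original
#' time index.
#'
#' @param x numeric series ordered by \code{dates}.
#' @param dates sampling dates (used for calendar conversion).
#' @param params a \linkS4class{RhythmScanParams}.
#' @return one-row data.frame: statistic, raw minimum p, corrected p, best
#'   period (time points and months), peak index and month, tie flag and the
#'   number of candidates scanned.
#' @export
detectRhythm <- function(x, dates, params = rhythmScanParams()) {
  if (all(is.na(x))) stop("all values missing")
  n <- length(x)
  if (length(dates) != n) stop("dates must match the series length")
  if (!anyNA(x)) {
    out <- rhythmScanCore(matrix(x, 1), as.Date(dates), params)
    return(out[, c("statistic", "p_raw", "p", "period_tp", "peak_index",
                   "period_months", "peak_month", "ties", "n_candidates")])
  }
  # missing values: per-candidate statistics with the original-index group
  # assignment; the Bonferroni count is the full (undeduplicated) grid
  cand <- candidateGrid(n, params)
  ties <- FALSE
  pvals <- numeric(nrow(cand))
  stats_ <- numeric(nrow(cand))
  for (ci in seq_len(nrow(cand))) {
    us <- umbrellaStatistic(x, cand$periodTp[ci], cand$peakK[ci],
                            cand$rotation[ci])
    ties <- ties || us$ties
    pvals[ci] <- exactNullPvalue(us$U, us$sizes, us$peakK,
                                 exactCap = params@exactCap)
    stats_[ci] <- us$U
  }
  bi <- which.min(pvals)
  peakIdx <- ((cand$peakK[bi] - 1L + cand$rotation[bi]) %%
                cand$periodTp[bi]) + 1L
  dates <- as.Date(dates)
  interval <- as.numeric(stats::median(diff(dates)))
  peakDate <- circularPeakDate(x, as.numeric(dates - dates[1]), dates[1],
                               cand$periodTp[bi] * interval)
  data.frame(statistic = stats_[bi], p_raw = pvals[bi],
             p = min(1, pvals[bi] * nrow(cand)),
             period_tp = cand$periodTp[bi], peak_index = peakIdx,
             period_months = cand$periodTp[bi] * interval / params@monthDays,
             peak_month = monthOf(peakDate),
             ties = ties, n_candidates = nrow(cand))
}

# expression-weighted circular phase: the first peak date of a series under
# a candidate period P (days), estimated by the circular mean of the
# sampling phase angle weighted by the series above its minimum
circularPeakDate <- function(x, dayOffsets, firstDate, periodDays) {
  keep <- !is.na(x)
  w <- x[keep] - min(x[keep])
  th <- 2 * pi * dayOffsets[keep] / periodDays
  if (sum(w) == 0) return(firstDate)
  frac <- (atan2(sum(w * sin(th)), sum(w * cos(th))) / (2 * pi)) %% 1
  firstDate + round(frac * periodDays)
}

# shared scan core: per-gene best candidate and Bonferroni-corrected p;
# the peak month is the scan's best period refined by the weighted circular
# phase over the whole series (the phase-group resolution alone is one
# sampling interval, about one month)
rhythmScanCore <- function(mat, dates, params) {
  n <- ncol(mat)
  engine <- scanEngine(n, params)
  sp <- scanPvalues(mat, engine)
  nc <- nrow(engine$cand)
  praw <- do.call(pmin, as.data.frame(sp$p))
  best <- max.col(-sp$p, ties.method = "first")
  p <- pmin(1, praw * nc)
  periodTp <- engine$cand$periodTp[best]
  peakIdx <- ((engine$cand$peakK[best] - 1L +
                 engine$cand$rotation[best]) %% periodTp) + 1L
  d0 <- as.numeric(dates - dates[1])
  interval <- as.numeric(stats::median(diff(dates)))
  peakDate <- as.Date(vapply(seq_len(nrow(mat)), function(g)
    as.numeric(circularPeakDate(mat[g, ], d0, dates[1],
                                periodTp[g] * interval)),
    numeric(1)), origin = "1970-01-01")
  ties <- apply(mat, 1, function(r) anyDuplicated(r) > 0)
  data.frame(
    statistic = sp$U[cbind(seq_len(nrow(mat)), best)],
    p_raw = praw, p = p, period_tp = periodTp, peak_index = peakIdx,
    period_months = periodTp * interval / params@monthDays,
    peak_month = monthOf(peakDate), peak_date = peakDate,
    ties = ties, n_candidates = nc, row.names = NULL)
}

#' Genome-wide rhythmicity scan
#'
#' Vectorized [detectRhythm()] over the rows of a normalized expression
#' matrix for one species/tissue series, followed by multiple-testing
#' adjustment across genes and period classification. Period (months) and
#' peak month are reported only for genes called rhythmic
#' (q below \code{qThreshold}).
#'
#' @param mat complete numeric matrix, genes x ordered time points.
#' @param dates sampling dates, one per column.
#' @param params a \linkS4class{RhythmScanParams}.
#' @return data.frame with one row per gene: \code{gene_id},
#'   \code{statistic}, \code{p_raw}, \code{p}, \code{q}, \code{period_tp},
#'   \code{peak_index}, \code{period_months}, \code{peak_month},
#'   \code{second_peak_month} (half-annual genes), \code{category} and
#'   \code{ties}.
#' @export
rhythmScan <- function(mat, dates, params = rhythmScanParams()) {
  mat <- as.matrix(mat)
  if (anyNA(mat))
    stop("rhythmScan needs a complete matrix; use detectRhythm per series")
  n <- ncol(mat)
  if (length(dates) != n) stop("dates must match the number of columns")
  dates <- as.Date(dates)
  core <- rhythmScanCore(mat, dates, params)
  q <- adjustQvalues(core$p, method = params@adjust)
  rhythmic <- q < params@qThreshold
  category <- ifelse(rhythmic, classifyPeriod(core$period_months),
                     "arrhythmic")
  interval <- as.numeric(stats::median(diff(dates)))
  second <- ifelse(category == "half-annual",
                   monthOf(core$peak_date + round(core$period_tp * interval)),
                   NA_integer_)
  data.frame(
    gene_id = if (is.null(rownames(mat))) sprintf("g%d", seq_len(nrow(mat)))
              else rownames(mat),
    statistic = core$statistic,
    p_raw = core$p_raw, p = core$p, q = q,
    period_tp = core$period_tp, peak_index = core$peak_index,
    period_months = ifelse(rhythmic, core$period_months, NA_real_),
    peak_month = ifelse(rhythmic, core$peak_month, NA_integer_),
    second_peak_month = second,
    category = category, ties = core$ties,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Permutation null for the rhythm scan
#'
#' Permutes time labels and recomputes the statistic, returning the
#' add-one-smoothed empirical tail probability. With \code{candidate} given,
#' the statistic is the umbrella U of that single (period, peak) candidate,
#' which estimates the same quantity as [exactNullPvalue()]; without it, the
#' statistic is the minimum raw p-value over all candidates, i.e. the null
#' distribution of the whole scan before Bonferroni correction (which the
#' corrected p-value bounds conservatively, since candidates overlap).
#'
#' @param x numeric series (no NAs).
#' @param params a \linkS4class{RhythmScanParams}.
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @param candidate optional list/vector with \code{periodTp} and
#'   \code{peakK}.
#' @return empirical p-value \code{(1 + #{perm >= obs}) / (nPerm + 1)}.
#' @export
permutationOracle <- function(x, params = rhythmScanParams(), nPerm = 1000,
                              seed = 1L, candidate = NULL) {
  if (anyNA(x)) stop("permutationOracle needs a complete series")
  set.seed(as.integer(seed))
  n <- length(x)
  perms <- t(vapply(seq_len(nPerm), function(i) sample(x), numeric(n)))
  if (!is.null(candidate)) {
    tp <- candidate$periodTp
    pk <- candidate$peakK
    rot <- candidate$rotation %||% 0L
    g <- ((seq_len(n) - 1L) %% tp) + 1L
    pos <- ((g - 1L - as.integer(rot)) %% tp) + 1L
    gi <- matrix(pos, n, n); gj <- t(gi)
    mvec <- as.numeric((gi < gj & gj <= pk) | (gi > gj & gj >= pk))
    uObs <- as.numeric(pairComparisons(matrix(x, 1)) %*% mvec)
    uPerm <- as.numeric(pairComparisons(perms) %*% mvec)
    return((1 + sum(uPerm >= uObs - 1e-9)) / (nPerm + 1))
  }
  engine <- scanEngine(n, params)
  pObs <- min(scanPvalues(matrix(x, 1), engine)$p)
  pPerm <- scanPvalues(perms, engine)$p
  pMin <- do.call(pmin, as.data.frame(pPerm))
  (1 + sum(pMin <= pObs + 1e-12)) / (nPerm + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- multiple testing and calendar conversion -----------------------------

# Lowest-slope estimate of the number of true null hypotheses: walk the
# slopes S_i = (1 - p_(i)) / (m + 1 - i) until they first decrease, then
# m0 = min(m, ceiling(1 / S_j + 1)) at the stopping index.
estimateNullCount <- function(p) {
  m <- length(p)
  if (m < 2) return(m)
  sp <- sort(p)
  s <- (1 - sp) / (m + 1 - seq_len(m))
  i <- 2L
  while (i <= m && s[i] >= s[i - 1]) i <- i + 1L
  if (i > m || s[i] <= 0) return(m)
  min(m, ceiling(1 / s[i] + 1))
}

#' Adaptive Benjamini-Hochberg q-values
#'
#' Plain BH, or adaptive BH in which the number of true nulls \code{m0} is
#' estimated by the lowest-slope rule and replaces \code{m} in the step-up
#' procedure. With \code{m0 = m} the adaptive procedure reduces to plain BH;
#' q-values are monotone nondecreasing in the p-value rank.
#'
#' @param p vector of p-values in [0, 1].
#' @param method \code{"ABH"} (default) or \code{"BH"}.
#' @return q-values in the original order.
#' @export
adjustQvalues <- function(p, method = c("ABH", "BH")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  m0 <- if (method == "ABH") estimateNullCount(p) else m
  o <- order(p)
  qs <- pmin(1, rev(cummin(rev(m0 * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- qs
  q
}

#' Convert scan output to calendar units
#'
#' The period in months is \code{periodTp * interval / (365.25 / 12)} where
#' the interval is the median sampling spacing in days. The peak month is
#' the Gregorian month of the peak phase group's position in the year: the
#' circular mean of the day-of-year over every sampling date assigned to the
#' peak group (indices congruent to \code{peakIndex} modulo
#' \code{periodTp}), which cancels the calendar drift of candidate periods
#' that do not divide the year evenly. With a single occurrence this is the
#' month of that sampling date.
#'
#' @param periodTp period in time points (vectorized with
#'   \code{peakIndex}).
#' @param peakIndex first time point of the peak phase group (1-based).
#' @param dates ordered sampling dates.
#' @param monthDays days per month (365.25 / 12).
#' @return list with \code{periodMonths} and \code{peakMonth}.
#' @export
toCalendar <- function(periodTp, peakIndex, dates, monthDays = 365.25 / 12) {
  dates <- as.Date(dates)
  if (any(peakIndex < 1 | peakIndex > length(dates)))
    stop("peak index out of range")
  interval <- as.numeric(stats::median(diff(dates)))
  doy <- as.POSIXlt(dates)$yday + 1
  ang <- 2 * pi * doy / 365.25
  peakMonth <- mapply(function(tp, pk) {
    occ <- seq.int(pk, length(dates), by = tp)
    a <- atan2(mean(sin(ang[occ])), mean(cos(ang[occ])))
    meanDoy <- (a / (2 * pi) * 365.25) %% 365.25
    monthOf(as.Date("2020-12-31") + pmax(1, ceiling(meanDoy)))
  }, periodTp, peakIndex)
  list(periodMonths = periodTp * interval / monthDays,
       peakMonth = as.integer(peakMonth))
}

#' Classify a period length
#'
#' Half-annual below 8 months, annual for 8--16 months inclusive, long
#' above 16 months.
#'
#' @param periodMonths period in months (> 0).
#' @return character vector of categories.
#' @export
classifyPeriod <- function(periodMonths) {
  if (any(periodMonths <= 0, na.rm = TRUE)) stop("period must be positive")
  ifelse(periodMonths < 8, "half-annual",
         ifelse(periodMonths <= 16, "annual", "long"))
}
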