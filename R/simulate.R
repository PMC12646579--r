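#' Configure the synthetic seasonal-expression generator
#'
#' Defaults emulate the four-species, two-tissue, four-weekly, two-year
#' evergreen Fagaceae sampling design: 27 time points 28 days apart, three
#' biological replicates per species except a single individual for
#' \code{Ledulis}, a majority of arrhythmic genes, annual rhythms dominating
#' the rhythmic fraction, and most annual genes phase-locked to a shared
#' winter (December--February) peak while the remainder diverge across
#' species during the growing season.
#'
#' @param nGenes number of genes.
#' @param fracAnnual,fracHalfAnnual,fracArrhythmic gene-category mixture;
#'   must sum to 1.
#' @param speciesNames,tissues labels of the simulated species and tissues.
#' @param nTimepoints,intervalDays,startDate the sampling calendar: samples
#'   are dated \code{startDate + i * intervalDays}.
#' @param replicates named integer vector: individuals per species.
#' @param amplitudeLog2 peak-to-mean oscillation amplitude on the log2 scale.
#' @param dispersion negative-binomial overdispersion (variance
#'   \code{mu + dispersion * mu^2}); 0 gives Poisson counts.
#' @param depth expected library size (sum of expected counts per sample).
#' @param winterLockFraction proportion of annual genes whose peak month is
#'   shared across species and drawn from December--February.
#' @param growingPhaseSdMonths SD (months) of the independent per-species
#'   phase offsets of non-locked rhythmic genes.
#' @param baselineSdLog SD of the log-normal spread of per-gene baseline
#'   abundances.
#' @param seed integer seed; identical configurations reproduce byte-identical
#'   datasets.
#' @return a validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(nGenes = 2000,
                      fracAnnual = 0.35,
                      fracHalfAnnual = 0.05,
                      fracArrhythmic = 0.60,
                      speciesNames = c("Qglauca", "Qacuta", "Ledulis", "Lglaber"),
                      tissues = c("leaf", "bud"),
                      nTimepoints = 27,
                      intervalDays = 28,
                      startDate = as.Date("2021-04-15"),
                      replicates = c(Qglauca = 3L, Qacuta = 3L,
                                     Ledulis = 1L, Lglaber = 3L),
                      amplitudeLog2 = 1.5,
                      dispersion = 0.1,
                      depth = 2e6,
                      winterLockFraction = 0.8,
                      growingPhaseSdMonths = 2,
                      baselineSdLog = 1.2,
                      seed = 1L) {
  if (is.null(names(replicates)))
    names(replicates) <- speciesNames[seq_along(replicates)]
  methods::new("SimConfig",
    nGenes = as.integer(nGenes),
    fracAnnual = fracAnnual, fracHalfAnnual = fracHalfAnnual,
    fracArrhythmic = fracArrhythmic,
    speciesNames = speciesNames, tissues = tissues,
    nTimepoints = as.integer(nTimepoints),
    intervalDays = as.integer(intervalDays),
    startDate = as.Date(startDate),
    replicates = vapply(replicates, as.integer, integer(1)),
    amplitudeLog2 = amplitudeLog2, dispersion = dispersion, depth = depth,
    winterLockFraction = winterLockFraction,
    growingPhaseSdMonths = growingPhaseSdMonths,
    baselineSdLog = baselineSdLog,
    seed = as.integer(seed))
}

#' Simulate a multi-species seasonal expression dataset with known truth
#'
#' Counts are negative-binomial with log2-mean
#' \code{log2(depth * baseline) + A * cos(2 * pi * (t - peak) / P)} for
#' rhythmic genes (P = 12 months annual, 6 months half-annual) and a flat
#' baseline for arrhythmic genes. Winter-locked annual genes share one peak
#' month across species drawn from December--February; the remaining
#' rhythmic genes draw a species-common growing-season base month plus
#' independent per-species offsets \code{round(N(0, growingPhaseSdMonths))}.
#' Tissues share a gene's phase. Gene lengths are log-uniform on
#' [300, 10000] bp.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with elements \code{dataset} (a
#'   \linkS4class{PhenologyExperiment}) and \code{truth} (data.frame with the
#'   true category, period, baseline, amplitude, lock status and per-species
#'   peak month of every gene).
#' @export
simulateDataset <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)
  nG <- config@nGenes
  sp <- config@speciesNames
  geneIds <- sprintf("g%05d", seq_len(nG))

  lengths <- round(exp(stats::runif(nG, log(300), log(10000))))
  weights <- stats::rlnorm(nG, meanlog = 0, sdlog = config@baselineSdLog)
  baseline <- weights / sum(weights)

  nAnn <- round(config@fracAnnual * nG)
  nHalf <- round(config@fracHalfAnnual * nG)
  nHalf <- min(nHalf, nG - nAnn)
  category <- rep("arrhythmic", nG)
  category[seq_len(nAnn)] <- "annual"
  if (nHalf > 0) category[nAnn + seq_len(nHalf)] <- "half-annual"
  category <- sample(category)   # shuffle so category is not tied to gene order

  rhythmic <- category != "arrhythmic"
  locked <- rep(FALSE, nG)
  locked[category == "annual"] <-
    stats::runif(sum(category == "annual")) < config@winterLockFraction

  peakMonth <- matrix(NA_integer_, nG, length(sp),
                      dimnames = list(geneIds, sp))
  for (g in seq_len(nG)) {
    if (!rhythmic[g]) next
    if (locked[g]) {
      peakMonth[g, ] <- sample(WINTER_MONTHS, 1)
    } else {
      base <- if (category[g] == "annual") sample(3:11, 1) else sample(1:12, 1)
      off <- round(stats::rnorm(length(sp), 0, config@growingPhaseSdMonths))
      peakMonth[g, ] <- wrapMonth(base + off)
    }
  }

  dates <- config@startDate + config@intervalDays * (0:(config@nTimepoints - 1))
  meta <- do.call(rbind, lapply(sp, function(s) {
    do.call(rbind, lapply(config@tissues, function(ti) {
      do.call(rbind, lapply(seq_len(config@replicates[[s]]), function(ind) {
        data.frame(
          sample_id = sprintf("%s_%s_ind%d_t%02d", s, ti, ind,
                              seq_along(dates)),
          species = s, tissue = ti, individual = ind, date = dates,
          stringsAsFactors = FALSE)
      }))
    }))
  }))

  periodDays <- ifelse(category == "annual", 365.25,
                       ifelse(category == "half-annual", 365.25 / 2, NA))
  amp <- ifelse(rhythmic, config@amplitudeLog2, 0)
  baseLog2 <- log2(config@depth * baseline)

  counts <- matrix(0L, nG, nrow(meta), dimnames = list(geneIds, meta$sample_id))
  anchorNum <- matrix(NA_real_, nG, length(sp), dimnames = list(NULL, sp))
  for (s in sp)
    anchorNum[rhythmic, s] <- as.numeric(monthAnchor(peakMonth[rhythmic, s]))
  size <- if (config@dispersion > 0) 1 / config@dispersion else Inf
  for (j in seq_len(nrow(meta))) {
    s <- meta$species[j]
    mu <- baseLog2
    if (any(rhythmic)) {
      delta <- as.numeric(meta$date[j]) - anchorNum[rhythmic, s]
      mu[rhythmic] <- mu[rhythmic] +
        amp[rhythmic] * cos(2 * pi * delta / periodDays[rhythmic])
    }
    muLin <- 2^mu
    counts[, j] <- if (is.finite(size))
      stats::rnbinom(nG, mu = muLin, size = size)
    else stats::rpois(nG, muLin)
  }

  truth <- data.frame(
    gene_id = geneIds, category = category,
    period_months = ifelse(category == "annual", 12,
                           ifelse(category == "half-annual", 6, NA)),
    locked = locked, baseline = baseline, amplitude = amp,
    stringsAsFactors = FALSE)
  for (s in sp) truth[[paste0("peak_month_", s)]] <- peakMonth[, s]

  dataset <- PhenologyExperiment(counts, lengths, meta[, -1])
  colnames(dataset) <- meta$sample_id
  list(dataset = dataset, truth = truth)
}

#' Simulate codon-aligned CDS pairs with controlled divergence
#'
#' Generates gap-free, stop-free pairs of equal-length coding sequences in
#' which synonymous and nonsynonymous single-base substitutions are placed
#' codon-wise at rates chosen so that NG86 counting recovers approximately
#' the requested \code{targetDs} and \code{omega = dN/dS}. Substitutions that
#' would create stop codons are never placed.
#'
#' @param nPairs number of ortholog pairs.
#' @param targetOmega,targetDs desired dN/dS ratio and synonymous divergence
#'   (Jukes--Cantor scale); both must be non-negative.
#' @param nCodons codons per sequence.
#' @param seed integer seed.
#' @return list with \code{pairs} (a \code{Biostrings::DNAStringSet} with
#'   names \code{"<pairID>|A"} / \code{"<pairID>|B"}) and \code{truth}
#'   (data.frame of per-pair substitution counts and targets).
#' @export
simulateCdsPairs <- function(nPairs, targetOmega = 0.2, targetDs = 0.5,
                             nCodons = 300, seed = 1L) {
  if (targetOmega < 0 || targetDs < 0)
    stop("targetOmega and targetDs must be non-negative")
  set.seed(as.integer(seed))
  tab <- codonTables()
  pS <- 0.75 * (1 - exp(-4 * targetDs / 3))
  pN <- 0.75 * (1 - exp(-4 * targetDs * targetOmega / 3))

  seqs <- character(2 * nPairs)
  nms <- character(2 * nPairs)
  truth <- data.frame(pair_id = sprintf("pair%04d", seq_len(nPairs)),
                      target_omega = targetOmega, target_ds = targetDs,
                      syn_subs = 0L, nonsyn_subs = 0L,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nPairs)) {
    a <- sample(tab$sense, nCodons, replace = TRUE)
    b <- a
    nSyn <- 0L; nNon <- 0L
    if (targetDs > 0) {
      sSites <- tab$synSites[a]
      doSyn <- stats::runif(nCodons) < pmin(0.95, pS * sSites)
      doNon <- stats::runif(nCodons) < pmin(0.95, pN * (3 - sSites))
      for (k in which(doSyn)) {
        nb <- tab$neighbors[[b[k]]]
        cand <- nb$mutant[nb$syn & !nb$stop]
        if (length(cand)) { b[k] <- cand[sample.int(length(cand), 1)]; nSyn <- nSyn + 1L }
      }
      for (k in which(doNon)) {
        nb <- tab$neighbors[[b[k]]]
        cand <- nb$mutant[!nb$syn & !nb$stop]
        if (length(cand)) { b[k] <- cand[sample.int(length(cand), 1)]; nNon <- nNon + 1L }
      }
    }
    truth$syn_subs[i] <- nSyn
    truth$nonsyn_subs[i] <- nNon
    seqs[2 * i - 1] <- paste(a, collapse = "")
    seqs[2 * i] <- paste(b, collapse = "")
    nms[2 * i - 1] <- paste0(truth$pair_id[i], "|A")
    nms[2 * i] <- paste0(truth$pair_id[i], "|B")
  }
  pairs <- Biostrings::DNAStringSet(seqs)
  names(pairs) <- nms
  list(pairs = pairs, truth = truth)
}

#' Write a simulated dataset to plain-text fixture files
#'
#' Emits \code{counts.tsv} (gene_id, length_bp, one column per sample),
#' \code{metadata.tsv} (sample_id, species, tissue, individual, ISO-8601
#' date), \code{truth.tsv}, and optionally \code{cds_pairs.fa}. The files
#' round-trip losslessly through [readExpressionTsv()].
#'
#' @param dataset a \linkS4class{PhenologyExperiment}.
#' @param truth truth data.frame from [simulateDataset()] (or NULL).
#' @param dir output directory (created if needed).
#' @param pairs optional \code{DNAStringSet} of CDS pairs.
#' @return invisibly, the paths written.
#' @export
writeFixture <- function(dataset, truth, dir, pairs = NULL) {
  if (nrow(dataset) == 0 || ncol(dataset) == 0)
    stop("cannot write an empty dataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  cnt <- SummarizedExperiment::assay(dataset, "counts")
  countsDf <- data.frame(gene_id = rownames(dataset),
                         length_bp = geneLengths(dataset),
                         cnt, check.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(dataset))
  metaDf <- data.frame(sample_id = colnames(dataset),
                       species = cd$species, tissue = cd$tissue,
                       individual = cd$individual,
                       date = format(cd$date, "%Y-%m-%d"))
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"))
  utils::write.table(countsDf, paths["counts"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(metaDf, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    paths["truth"] <- file.path(dir, "truth.tsv")
    utils::write.table(truth, paths["truth"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(pairs)) {
    paths["pairs"] <- file.path(dir, "cds_pairs.fa")
    Biostrings::writeXStringSet(pairs, paths["pairs"])
  }
  invisible(paths)
}
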