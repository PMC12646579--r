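#' Run the molecular-phenology pipeline end to end
#'
#' Executes the fixed stage order on a count dataset: RPK computation,
#' per-species low-expression filtering, per-species GeTMM normalization,
#' replicate averaging with log2 transform, a rhythmicity scan per
#' (species, tissue) series, the monthly divergence profile over all
#' species pairs with the across-month comparison, and per-gene
#' cross-species correlations. Every stage logs its input/output dimensions
#' and the run is fully described by the returned manifest.
#'
#' @param dataset a \linkS4class{PhenologyExperiment}.
#' @param params a \linkS4class{RhythmScanParams}.
#' @param rpkThreshold per-species mean-RPK filter threshold.
#' @param trimM,trimA TMM trim fractions.
#' @param divergenceThreshold circular month difference counted as
#'   divergent.
#' @param genus optional named species-to-genus map.
#' @param outDir optional directory; when given, stage TSVs are written.
#' @param verbose emit one log line per stage.
#' @return list with \code{normalized} (SummarizedExperiment),
#'   \code{filter}, \code{variability}, \code{rhythm} (named per
#'   species_tissue), \code{profile}, \code{profileSummary},
#'   \code{monthComparison}, \code{correlations} and \code{manifest}.
#' @export
runPipeline <- function(dataset, params = rhythmScanParams(),
                        rpkThreshold = 1, trimM = 0.30, trimA = 0.05,
                        divergenceThreshold = 2, genus = NULL,
                        outDir = NULL, verbose = TRUE) {
  log_ <- function(...) if (verbose) message("[molphen] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  cd <- as.data.frame(SummarizedExperiment::colData(dataset))

  rpk <- stage("rpk", computeRPK(dataset))
  log_("rpk: ", nrow(rpk), " genes x ", ncol(rpk), " samples")

  flt <- stage("filter", filterLowExpression(rpk, cd$species, rpkThreshold))
  log_("filter: kept ", length(flt$keep), " of ", nrow(rpk), " genes")

  getmm <- matrix(NA_real_, length(flt$keep), ncol(rpk),
                  dimnames = list(flt$keep, colnames(rpk)))
  factors <- numeric(ncol(rpk))
  stage("getmm", for (s in unique(cd$species)) {
    idx <- which(cd$species == s)
    gn <- getmmNormalize(rpk[flt$keep, idx, drop = FALSE],
                         trimM = trimM, trimA = trimA)
    getmm[, idx] <- gn$getmm
    factors[idx] <- gn$factors
  })
  log_("getmm: per-species TMM factors in [",
       round(min(factors), 3), ", ", round(max(factors), 3), "]")

  normalized <- stage("log_average", logAverage(getmm, cd))
  log_("log_average: ", ncol(normalized), " (species, tissue, date) columns")

  vr <- stage("variability",
              variabilityRatio(SummarizedExperiment::assay(normalized)))
  log_("variability: genome/gene CV ratio = ", round(vr$ratio, 2))

  ncd <- SummarizedExperiment::colData(normalized)
  nmat <- SummarizedExperiment::assay(normalized)
  seriesKeys <- unique(paste(ncd$species, ncd$tissue, sep = "_"))
  rhythm <- list()
  stage("rhythm", for (keyi in seriesKeys) {
    parts <- strsplit(keyi, "_")[[1]]
    idx <- which(ncd$species == parts[1] & ncd$tissue == parts[2])
    idx <- idx[order(ncd$date[idx])]
    rhythm[[keyi]] <- rhythmScan(nmat[, idx, drop = FALSE],
                                 ncd$date[idx], params)
  })
  log_("rhythm: scanned ", length(rhythm), " species x tissue series")

  profile <- profileSummary <- monthComparison <- NULL
  species <- unique(ncd$species)
  if (length(species) >= 2) {
    byTissue <- list()
    for (ti in unique(ncd$tissue)) {
      rl <- rhythm[paste(species, ti, sep = "_")]
      names(rl) <- species
      rl <- rl[!vapply(rl, is.null, logical(1))]
      if (length(rl) >= 2) {
        pr <- stage("divergence",
                    monthlyProfile(rl, genus = genus,
                                   threshold = divergenceThreshold))
        pr$tissue <- ti
        byTissue[[ti]] <- pr
      }
    }
    if (length(byTissue)) {
      profile <- do.call(rbind, byTissue)
      profileSummary <- summarizeProfile(profile)
      monthComparison <- tryCatch(compareMonths(profile),
                                  error = function(e) NULL)
      log_("divergence: profile over ",
           length(unique(profile$pair)), " ordered pairs")
    }
  }

  correlations <- NULL
  if (length(species) >= 2) {
    correlations <- list()
    stage("correlate", for (ti in unique(ncd$tissue)) {
      for (i in seq_along(species)) for (j in seq_along(species)) {
        if (i >= j) next
        ia <- which(ncd$species == species[i] & ncd$tissue == ti)
        ib <- which(ncd$species == species[j] & ncd$tissue == ti)
        if (!length(ia) || !length(ib) || length(ia) != length(ib)) next
        ia <- ia[order(ncd$date[ia])]; ib <- ib[order(ncd$date[ib])]
        al <- alignWindows(nmat[, ia, drop = FALSE], nmat[, ib, drop = FALSE])
        tabl <- perGeneCorrelation(al)
        tabl$pair <- paste(species[i], species[j], sep = "-")
        tabl$tissue <- ti
        correlations[[paste(species[i], species[j], ti, sep = "_")]] <- tabl
      }
    })
    correlations <- do.call(rbind, correlations)
    rownames(correlations) <- NULL
    log_("correlate: ", length(unique(correlations$pair)),
         " unordered pairs per tissue")
  }

  manifest <- list(
    n_genes_in = nrow(dataset), n_samples = ncol(dataset),
    n_genes_kept = length(flt$keep),
    rpk_threshold = rpkThreshold, trim_m = trimM, trim_a = trimA,
    scan = list(center_period = params@centerPeriod,
                period_delta = params@periodDelta,
                peak_border = params@peakBorder,
                q_threshold = params@qThreshold, adjust = params@adjust),
    divergence_threshold = divergenceThreshold)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeNormalizedTsv(nmat, file.path(outDir, "normalized.tsv"))
    for (keyi in names(rhythm))
      utils::write.table(rhythm[[keyi]],
                         file.path(outDir, paste0("rhythm_", keyi, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(profile))
      utils::write.table(profile, file.path(outDir, "divergence_profile.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(correlations))
      utils::write.table(correlations,
                         file.path(outDir, "correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    saveRDSFree <- file.path(outDir, "manifest.json")
    writeLines(manifestJson(manifest), saveRDSFree)
  }

  list(normalized = normalized, filter = flt, factors = factors,
       variability = vr, rhythm = rhythm, profile = profile,
       profileSummary = profileSummary, monthComparison = monthComparison,
       correlations = correlations, manifest = manifest)
}

# minimal JSON writer for the manifest (flat lists of scalars/vectors)
manifestJson <- function(x, indent = "") {
  enc <- function(v) {
    if (is.list(v)) return(manifestJson(v, paste0(indent, "  ")))
    if (is.character(v)) v <- paste0('"', v, '"')
    if (length(v) == 1) as.character(v)
    else paste0("[", paste(v, collapse = ", "), "]")
  }
  body <- vapply(names(x), function(nm)
    paste0(indent, '  "', nm, '": ', enc(x[[nm]])), character(1))
  paste0("{\n", paste(body, collapse = ",\n"), "\n", indent, "}")
}
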