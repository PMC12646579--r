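# shared builders for the test suite; everything is generated in code

fourWeekly <- function(n = 27, start = "2021-04-15")
  as.Date(start) + 28 * (0:(n - 1))

# minimal one-species config for fast unit runs
smallConfig <- function(nGenes = 50, seed = 1, ...) {
  simConfig(nGenes = nGenes, speciesNames = "Qglauca", tissues = "bud",
            replicates = c(Qglauca = 1L), seed = seed, ...)
}

# tiny PhenologyExperiment built by hand
toyExperiment <- function(counts = NULL, nGenes = 4, nSamples = 6) {
  if (is.null(counts)) {
    counts <- matrix(seq_len(nGenes * nSamples) * 3, nGenes, nSamples)
  }
  rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  meta <- data.frame(species = "A", tissue = "bud", individual = 1,
                     date = fourWeekly(ncol(counts)))
  PhenologyExperiment(counts, rep(1000, nrow(counts)), meta)
}

# all compositions of n into k >= 2 positive parts
allCompositions <- function(n) {
  rec <- function(n) {
    if (n == 0) return(list(integer(0)))
    out <- list()
    for (first in seq_len(n))
      for (rest in rec(n - first))
        out[[length(out) + 1L]] <- c(first, rest)
    out
  }
  Filter(function(x) length(x) >= 2, rec(n))
}

# all permutations of 1..n as a matrix (n! rows)
permMatrix <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- permMatrix(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, p + (p >= i))))
}

# umbrella pair mask for explicit group sizes and peak position
umbrellaMask <- function(sizes, peakK) {
  g <- rep(seq_along(sizes), sizes)
  n <- length(g)
  gi <- matrix(g, n, n); gj <- t(gi)
  (gi < gj & gj <= peakK) | (gi > gj & gj >= peakK)
}
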