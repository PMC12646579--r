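# Codon bookkeeping shared by the CDS simulator and the NG86 estimator.
# Tables are built once per session from the standard genetic code.

.codonEnv <- new.env(parent = emptyenv())

codonTables <- function() {
  if (!is.null(.codonEnv$tab)) return(.codonEnv$tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  names(aa) <- codons
  sense <- codons[aa != "*"]
  bases <- c("A", "C", "G", "T")

  # all single-base neighbours of every codon, annotated
  neighbors <- lapply(codons, function(cd) {
    sp <- strsplit(cd, "")[[1]]
    out <- list()
    for (pos in 1:3) {
      for (b in setdiff(bases, sp[pos])) {
        mut <- sp
        mut[pos] <- b
        mut <- paste(mut, collapse = "")
        out[[length(out) + 1L]] <- data.frame(
          mutant = mut, pos = pos,
          syn = aa[[mut]] == aa[[cd]],
          stop = aa[[mut]] == "*",
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, out)
  })
  names(neighbors) <- codons

  # NG86 synonymous site count per sense codon: at each position the codon
  # carries one site, split by the fraction of non-stop single-base mutants
  # that are synonymous (mutations to stops are dropped from the denominator)
  synSites <- vapply(sense, function(cd) {
    nb <- neighbors[[cd]]
    s <- 0
    for (pos in 1:3) {
      at <- nb[nb$pos == pos & !nb$stop, , drop = FALSE]
      if (nrow(at)) s <- s + sum(at$syn) / nrow(at)
    }
    s
  }, numeric(1))

  .codonEnv$tab <- list(aa = aa, sense = sense, neighbors = neighbors,
                        synSites = synSites)
  .codonEnv$tab
}
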