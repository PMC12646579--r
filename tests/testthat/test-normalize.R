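test_that("RPK is counts per kilobase of gene length", {
  cnt <- matrix(c(100, 50, 0), 3, 1,
                dimnames = list(c("a", "b", "c"), "s1"))
  rpk <- computeRPK(cnt, lengths = c(1000, 2000, 500))
  expect_equal(unname(rpk[, 1]), c(100, 25, 0))
  expect_error(computeRPK(cnt, lengths = c(1000, 0, 500)), "positive")
})

test_that("the low-expression filter drops below-threshold genes in any species", {
  rpk <- rbind(
    g1 = c(0.5, 0.5, 10, 10),   # mean 0.5 in species A -> dropped
    g2 = c(1.0, 1.0, 1.0, 1.0), # exactly at threshold -> kept
    g3 = c(5, 5, 5, 5))
  colnames(rpk) <- paste0("s", 1:4)
  sp <- c("A", "A", "B", "B")
  out <- filterLowExpression(rpk, sp)
  expect_setequal(out$keep, c("g2", "g3"))
  expect_equal(out$drop, "g1")
  expect_equal(out$report["g1", "A"], 0.5)
  expect_error(filterLowExpression(rpk, c("A", "A", "B")), "every sample")
})

test_that("GeTMM factors are 1 for identical or depth-scaled libraries", {
  rpk <- matrix(rep(c(10, 100, 1000), 3), 3, 3,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  out <- getmmNormalize(rpk)
  expect_equal(unname(out$factors), rep(1, 3), tolerance = 1e-12)
  expect_equal(out$getmm[, 1], out$getmm[, 2])

  scaled <- sweep(rpk, 2, c(1, 2, 5), "*")
  out2 <- getmmNormalize(scaled)
  expect_equal(out2$getmm[, 1], out2$getmm[, 2], tolerance = 1e-9)
  expect_equal(out2$getmm[, 1], out2$getmm[, 3], tolerance = 1e-9)
})

test_that("GeTMM matches the hand-computed 3-gene toy", {
  cnt <- matrix(c(10, 100, 1000, 20, 200, 2000), 3, 2,
                dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  rpk <- computeRPK(cnt, lengths = rep(1000, 3))  # 1 kb: RPK == counts
  out <- getmmNormalize(rpk)
  expect_equal(unname(out$factors[1] / out$factors[2]), 1, tolerance = 1e-9)
  expected <- c(10, 100, 1000) / 1110 * 1e6
  expect_equal(unname(out$getmm[, 1]), expected, tolerance = 1e-9)
  expect_equal(unname(out$getmm[, 2]), expected, tolerance = 1e-9)
})

test_that("GeTMM column sums times factors equal one million", {
  set.seed(42)
  rpk <- matrix(rexp(500 * 6, rate = 0.01), 500, 6,
                dimnames = list(paste0("g", 1:500), paste0("s", 1:6)))
  out <- getmmNormalize(rpk)
  expect_equal(unname(colSums(out$getmm) * out$factors), rep(1e6, 6),
               tolerance = 1e-6)
  expect_error(getmmNormalize(rpk[, 1, drop = FALSE]), "two samples")
  rpk0 <- rpk; rpk0[, 2] <- 0
  expect_error(getmmNormalize(rpk0), "zero total")
})

test_that("gene order does not affect normalization", {
  set.seed(7)
  rpk <- matrix(rexp(200 * 4, 0.01), 200, 4,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:4)))
  out <- getmmNormalize(rpk)
  perm <- sample(nrow(rpk))
  outP <- getmmNormalize(rpk[perm, ])
  expect_equal(outP$getmm, out$getmm[perm, ], tolerance = 1e-12)
})

test_that("replicate averaging happens before the log transform", {
  getmm <- matrix(c(3, 5, 7), 1, 3, dimnames = list("g1", paste0("s", 1:3)))
  meta <- data.frame(species = "A", tissue = "bud",
                     date = as.Date("2021-01-01"))
  meta <- meta[rep(1, 3), ]
  se <- logAverage(getmm, meta)
  expect_equal(unname(SummarizedExperiment::assay(se)[1, 1]), log2(6))

  single <- logAverage(matrix(7, 1, 1, dimnames = list("g1", "s1")),
                       data.frame(species = "A", tissue = "bud",
                                  date = as.Date("2021-01-01")))
  expect_equal(unname(SummarizedExperiment::assay(single)[1, 1]), log2(8))

  zero <- logAverage(matrix(0, 1, 2, dimnames = list("g1", c("a", "b"))),
                     data.frame(species = "A", tissue = "bud",
                                date = as.Date("2021-01-01"))[c(1, 1), ])
  expect_equal(unname(SummarizedExperiment::assay(zero)[1, 1]), 0)
})

test_that("variability ratio compares pooled to per-gene variation", {
  one <- matrix(c(1, 2, 3, 4), 1, 4, dimnames = list("g1", NULL))
  expect_equal(variabilityRatio(one)$ratio, 1)

  const <- matrix(rep(c(1, 5, 9), each = 4), 3, 4, byrow = TRUE,
                  dimnames = list(paste0("g", 1:3), NULL))
  vr <- variabilityRatio(const)
  expect_true(is.na(vr$ratio))

  set.seed(1)
  mu <- rlnorm(1000, 0, 1)
  mat <- t(vapply(mu, function(m) rlnorm(20, log(m), 0.1), numeric(20)))
  rownames(mat) <- paste0("g", 1:1000)
  vr2 <- variabilityRatio(mat)
  expect_gt(vr2$ratio, 3)

  flagged <- variabilityRatio(rbind(g1 = c(0, 0, 0), g2 = c(1, 2, 3)))
  expect_true(flagged$perGene$flagged[1])
  expect_false(flagged$perGene$flagged[2])
})

test_that("normalized matrices round-trip through the tagged TSV format", {
  dir <- withr::local_tempdir()
  mat <- matrix(rnorm(12), 3, 4,
                dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  path <- file.path(dir, "norm.tsv")
  writeNormalizedTsv(mat, path)
  expect_equal(readNormalizedTsv(path), mat, tolerance = 1e-12)
  plain <- file.path(dir, "plain.tsv")
  write.table(mat, plain, sep = "\t")
  expect_error(readNormalizedTsv(plain), "not a molphen")
})
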