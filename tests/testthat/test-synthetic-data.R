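test_that("identical configurations reproduce byte-identical datasets", {
  cfg <- smallConfig(nGenes = 30, seed = 11)
  a <- simulateDataset(cfg)
  b <- simulateDataset(cfg)
  expect_identical(SummarizedExperiment::assay(a$dataset),
                   SummarizedExperiment::assay(b$dataset))
  expect_identical(a$truth, b$truth)
  expect_identical(geneLengths(a$dataset), geneLengths(b$dataset))

  p1 <- simulateCdsPairs(5, 0.3, 0.4, nCodons = 50, seed = 4)
  p2 <- simulateCdsPairs(5, 0.3, 0.4, nCodons = 50, seed = 4)
  expect_identical(as.character(p1$pairs), as.character(p2$pairs))
})

test_that("category mixture and phase structure follow the configuration", {
  arr <- simulateDataset(smallConfig(nGenes = 40, fracAnnual = 0,
                                     fracHalfAnnual = 0, fracArrhythmic = 1,
                                     seed = 2))
  expect_true(all(arr$truth$category == "arrhythmic"))
  expect_true(all(is.na(arr$truth$peak_month_Qglauca)))

  cfg <- simConfig(nGenes = 200, fracAnnual = 1, fracHalfAnnual = 0,
                   fracArrhythmic = 0, winterLockFraction = 1,
                   tissues = "bud",
                   replicates = c(Qglauca = 1L, Qacuta = 1L,
                                  Ledulis = 1L, Lglaber = 1L),
                   speciesNames = c("Qglauca", "Qacuta",
                                    "Ledulis", "Lglaber"),
                   seed = 3)
  sim <- simulateDataset(cfg)
  pk <- sim$truth[, grep("^peak_month_", names(sim$truth))]
  # fully locked: one shared winter month across species for every gene
  expect_true(all(apply(pk, 1, function(r) length(unique(r)) == 1)))
  expect_true(all(pk[, 1] %in% c(12, 1, 2)))
})

test_that("invalid configurations are rejected", {
  expect_error(smallConfig(fracAnnual = 0.5, fracHalfAnnual = 0.5,
                           fracArrhythmic = 0.5), "sum to 1")
  expect_error(smallConfig(nTimepoints = 3), "nTimepoints")
  expect_error(simulateCdsPairs(2, targetOmega = -1, targetDs = 0.1),
               "non-negative")
  expect_error(simulateCdsPairs(2, targetOmega = 0.2, targetDs = -0.1),
               "non-negative")
})

test_that("counts are overdispersed relative to Poisson at high means", {
  cfg <- smallConfig(nGenes = 2000, fracAnnual = 0, fracHalfAnnual = 0,
                     fracArrhythmic = 1, dispersion = 0.1, depth = 1e6,
                     seed = 5)
  sim <- simulateDataset(cfg)
  cnt <- SummarizedExperiment::assay(sim$dataset)
  mu <- rowMeans(cnt)
  v <- apply(cnt, 1, stats::var)
  hi <- mu > 100
  expect_gt(sum(hi), 100)
  # NB variance mu + 0.1 mu^2 dwarfs Poisson variance mu at high means
  expect_gt(mean(v[hi] > 2 * mu[hi]), 0.95)
})

test_that("count marginals match the configured baseline for arrhythmic genes", {
  cfg <- smallConfig(nGenes = 300, fracAnnual = 0, fracHalfAnnual = 0,
                     fracArrhythmic = 1, dispersion = 0.05, depth = 1e6,
                     seed = 6)
  sim <- simulateDataset(cfg)
  cnt <- SummarizedExperiment::assay(sim$dataset)
  base <- sim$truth$baseline
  n <- ncol(cnt)
  se <- sqrt((base * cfg@depth + cfg@dispersion * (base * cfg@depth)^2) / n)
  dev <- abs(rowMeans(cnt) - base * cfg@depth)
  expect_gt(mean(dev <= 3 * se), 0.97)
})

test_that("the noiseless mean curve peaks at the truth-table month", {
  cfg <- smallConfig(nGenes = 50, fracAnnual = 1, fracHalfAnnual = 0,
                     fracArrhythmic = 0, seed = 7)
  sim <- simulateDataset(cfg)
  tr <- sim$truth
  grid <- seq(as.Date("2021-06-01"), as.Date("2022-05-31"), by = "day")
  for (i in seq_len(10)) {
    anchor <- as.Date(sprintf("2021-%02d-15", tr$peak_month_Qglauca[i]))
    mu <- cos(2 * pi * as.numeric(grid - anchor) / 365.25)
    peakMonth <- as.integer(format(grid[which.max(mu)], "%m"))
    expect_equal(peakMonth, tr$peak_month_Qglauca[i])
  }
})

test_that("CDS pairs are aligned, stop-free, and identical at zero divergence", {
  p0 <- simulateCdsPairs(4, targetOmega = 0.5, targetDs = 0, nCodons = 40,
                         seed = 8)
  w <- Biostrings::width(p0$pairs)
  expect_true(all(w == 120))
  expect_identical(as.character(p0$pairs[[1]]), as.character(p0$pairs[[2]]))
  aa <- Biostrings::translate(p0$pairs)
  expect_false(any(grepl("\\*", as.character(aa))))

  p1 <- simulateCdsPairs(10, targetOmega = 0.2, targetDs = 0.4,
                         nCodons = 100, seed = 9)
  aa1 <- Biostrings::translate(p1$pairs)
  expect_false(any(grepl("\\*", as.character(aa1))))
  expect_true(all(Biostrings::width(p1$pairs) %% 3 == 0))
})

test_that("fixtures round-trip losslessly through the readers", {
  dir <- withr::local_tempdir()
  sim <- simulateDataset(smallConfig(nGenes = 20, seed = 10))
  paths <- writeFixture(sim$dataset, sim$truth, dir)
  back <- readExpressionTsv(paths[["counts"]], paths[["metadata"]])
  expect_equal(SummarizedExperiment::assay(back, "counts"),
               SummarizedExperiment::assay(sim$dataset, "counts"))
  expect_equal(geneLengths(back), geneLengths(sim$dataset))
  expect_equal(sampleDates(back), sampleDates(sim$dataset))

  empty <- sim$dataset[integer(0), ]
  expect_error(writeFixture(empty, NULL, dir), "empty")
})
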