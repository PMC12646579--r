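test_that("umbrella statistic scores rise-fall concordance with midrank ties", {
  up <- umbrellaStatistic(c(1, 2, 3, 2, 1), 5, 3)
  expect_equal(up$U, 6)
  expect_equal(up$Umax, 6)

  down <- umbrellaStatistic(c(3, 2, 1, 2, 3), 5, 3)
  expect_equal(down$U, 0)

  const <- umbrellaStatistic(c(2, 2, 2, 2, 2), 5, 3)
  expect_equal(const$U, 3)          # six counted pairs, each ties at 0.5
  expect_true(const$ties)

  expect_error(umbrellaStatistic(1:4, 5, 6), "peakK")
  expect_error(umbrellaStatistic(1:4, 5, 3), "shorter")
})

test_that("rotation relabels the phase origin without changing the physics", {
  x <- c(5, 1, 2, 9, 7, 4, 6, 3, 8, 2, 7, 1)
  # rotating the series by r steps and rotating the group order by r are the
  # same operation for a full-period series
  for (rot in 1:3) {
    a <- umbrellaStatistic(x, 4, 2, rotation = rot)
    b <- umbrellaStatistic(c(x[-seq_len(rot)], x[seq_len(rot)]), 4, 2,
                           rotation = 0)
    expect_equal(a$U, b$U)
  }
  expect_equal(umbrellaStatistic(x, 4, 2, rotation = 0)$U,
               umbrellaStatistic(x, 4, 2)$U)
})

test_that("exact null matches full enumeration on small configurations", {
  # the spec's flagship case: five singleton groups, peak in the middle
  expect_equal(exactNullPvalue(6, rep(1, 5), 3), 6 / 120)
  expect_equal(exactNullPvalue(0, rep(1, 5), 3), 1)
  expect_error(exactNullPvalue(7, rep(1, 5), 3), "outside")

  set.seed(3)
  for (trial in 1:6) {
    n <- sample(4:6, 1)
    comps <- allCompositions(n)
    sizes <- comps[[sample(length(comps), 1)]]
    pk <- sample(seq_along(sizes), 1)
    g <- rep(seq_along(sizes), sizes)
    pm <- permMatrix(n)
    mask <- umbrellaMask(sizes, pk)
    U <- apply(pm, 1, function(r)
      sum(outer(r, r, "<")[mask]))
    for (u in 0:max(U))
      expect_equal(exactNullPvalue(u, sizes, pk), mean(U >= u),
                   tolerance = 1e-12)
  }
})

test_that("normal approximation agrees with the exact null at moderate n", {
  sizes <- rep(3, 10)  # n = 30
  pk <- 6
  mo <- molphen:::umbrellaNullMoments(sizes, pk)
  for (u in round(mo["mean"] + c(-1, 0, 1, 2) * sqrt(mo["var"]))) {
    pe <- exactNullPvalue(u, sizes, pk, exactCap = 40L)
    pa <- exactNullPvalue(u, sizes, pk, exactCap = 10L)
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("the scan is invariant to shifts and positive scalings", {
  set.seed(5)
  x <- rnorm(27)
  dates <- fourWeekly(27)
  r0 <- detectRhythm(x, dates)
  r1 <- detectRhythm(3 * x + 10, dates)
  expect_equal(r0$statistic, r1$statistic)
  expect_equal(r0$p, r1$p)
  expect_equal(r0$period_tp, r1$period_tp)
})

test_that("a noiseless annual cosine is detected at the right period", {
  dates <- fourWeekly(27)
  x <- cos(2 * pi * as.numeric(dates - as.Date("2021-12-15")) / 365.25)
  r <- detectRhythm(x, dates)
  expect_true(r$period_tp %in% 11:14)
  expect_lt(r$p, 0.01)
  expect_true(r$peak_month %in% c(11, 12, 1))

  const <- detectRhythm(rep(1, 27), dates)
  expect_equal(const$p, 1)
})

test_that("missing values are dropped while phase groups keep the time index", {
  dates <- fourWeekly(27)
  x <- cos(2 * pi * as.numeric(dates - as.Date("2021-12-15")) / 365.25)
  xm <- x; xm[c(5, 17)] <- NA
  r <- detectRhythm(xm, dates)
  expect_lt(r$p, 0.01)
  expect_error(detectRhythm(rep(NA_real_, 27), dates), "missing")
})

test_that("permutation oracle agrees with the exact null per candidate", {
  set.seed(9)
  x <- rnorm(12)
  us <- umbrellaStatistic(x, 4, 2, rotation = 1)
  pExact <- exactNullPvalue(us$U, us$sizes, us$peakK)
  pPerm <- permutationOracle(x, nPerm = 4000, seed = 2,
                             candidate = list(periodTp = 4, peakK = 2,
                                              rotation = 1))
  se <- sqrt(pExact * (1 - pExact) / 4000)
  expect_lt(abs(pPerm - pExact), 3 * se + 1e-3)

  expect_equal(permutationOracle(rep(2, 12), nPerm = 200, seed = 1,
                                 candidate = list(periodTp = 4, peakK = 2)),
               1)
  p1 <- permutationOracle(x, nPerm = 300, seed = 7)
  p2 <- permutationOracle(x, nPerm = 300, seed = 7)
  expect_identical(p1, p2)
})

test_that("the corrected scan p-value conservatively bounds the scan null", {
  set.seed(21)
  x <- rnorm(14)
  pFull <- permutationOracle(x, nPerm = 500, seed = 3)
  pCorr <- detectRhythm(x, fourWeekly(14))$p
  expect_lte(pFull, pCorr + 0.05)
})

test_that("BH and adaptive BH q-values behave as step-up procedures", {
  p <- c(0.001, 0.01, 0.02, 0.8)
  expect_equal(adjustQvalues(p, "BH"), p.adjust(p, "BH"))

  same <- rep(0.3, 5)
  expect_true(all(adjustQvalues(same) == adjustQvalues(same)[1]))

  # slopes nondecreasing -> m0 = m -> ABH reduces to plain BH
  pMono <- c(0.5, 0.6, 0.7)
  expect_equal(adjustQvalues(pMono, "ABH"), p.adjust(pMono, "BH"))

  # q is monotone in p-rank and bounded by [0, 1]
  set.seed(2)
  pr <- runif(100)
  q <- adjustQvalues(pr)
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(diff(q[order(pr)]) >= -1e-12))
  # with strong signal ABH is at least as powerful as BH
  pSig <- c(runif(50, 0, 1e-4), runif(50))
  expect_true(all(adjustQvalues(pSig, "ABH") <= adjustQvalues(pSig, "BH") + 1e-12))
  expect_error(adjustQvalues(c(0.5, 1.2)), "0, 1")
  expect_length(adjustQvalues(numeric(0)), 0)
})

test_that("calendar conversion uses the sampling span and Gregorian months", {
  dates <- fourWeekly(27)
  cal13 <- toCalendar(13, 1, dates)
  expect_equal(cal13$periodMonths, 13 * 28 / (365.25 / 12), tolerance = 1e-9)
  cal6 <- toCalendar(6, 1, dates)
  expect_equal(cal6$periodMonths, 6 * 28 / (365.25 / 12), tolerance = 1e-9)

  one <- toCalendar(27, 10, dates)  # single occurrence: month of that date
  expect_equal(one$peakMonth, as.integer(format(dates[10], "%m")))
  expect_error(toCalendar(13, 28, dates), "out of range")
})

test_that("periods classify as half-annual, annual, or long at the stated bounds", {
  expect_equal(classifyPeriod(6), "half-annual")
  expect_equal(classifyPeriod(c(8, 16)), c("annual", "annual"))
  expect_equal(classifyPeriod(16.5), "long")
  expect_error(classifyPeriod(0), "positive")
})

test_that("rhythmScan matches detectRhythm and classifies by q-threshold", {
  dates <- fourWeekly(27)
  set.seed(31)
  sig <- cos(2 * pi * as.numeric(dates - as.Date("2022-01-15")) / 365.25)
  mat <- rbind(a = sig + rnorm(27, 0, 0.2),
               b = rnorm(27),
               c = sig * 2 + rnorm(27, 0, 0.2))
  res <- rhythmScan(mat, dates)
  single <- detectRhythm(mat["a", ], dates)
  expect_equal(res$p[1], single$p)
  expect_equal(res$period_tp[1], single$period_tp)
  expect_true(all(res$category[c(1, 3)] == "annual"))
  expect_equal(res$category[2], "arrhythmic")
  expect_true(is.na(res$peak_month[2]))
  expect_true(circularMonthDiff(res$peak_month[1], 1) <= 1)
})
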