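test_that("month differences are circular, symmetric, and bounded by 6", {
  expect_equal(circularMonthDiff(1, 12), 1)
  expect_equal(circularMonthDiff(4, 10), 6)
  expect_equal(circularMonthDiff(3, 3), 0)
  expect_equal(circularMonthDiff(2, 11), circularMonthDiff(11, 2))
  expect_error(circularMonthDiff(0, 5), "1..12")
  expect_error(circularMonthDiff(3, 13), "1..12")
})

test_that("divergence index counts shifted peaks per reference month", {
  genes <- paste0("g", 1:3)
  pa <- setNames(c(1, 1, 1), genes)

  same <- divergenceIndex(pa, pa)
  expect_equal(same$D[same$month == 1], 0)
  expect_true(all(is.na(same$D[same$month != 1])))  # undefined, not 0

  shifted <- divergenceIndex(pa, setNames(c(7, 7, 7), genes))
  expect_equal(shifted$D[shifted$month == 1], 1)

  toy <- divergenceIndex(pa, setNames(c(1, 2, 4), genes))
  expect_equal(toy$D[toy$month == 1], 1 / 3)   # shifts 0, 1, 3; threshold 2
  expect_equal(toy$n_total[toy$month == 1], 3)
})

test_that("divergence index is monotone in the threshold and label-invariant", {
  set.seed(4)
  genes <- paste0("g", 1:200)
  pa <- setNames(sample(1:12, 200, TRUE), genes)
  pb <- setNames(sample(1:12, 200, TRUE), genes)
  d2 <- divergenceIndex(pa, pb, threshold = 2)
  d3 <- divergenceIndex(pa, pb, threshold = 3)
  ok <- !is.na(d2$D)
  expect_true(all(d3$D[ok] <= d2$D[ok] + 1e-12))

  perm <- sample(genes)
  dp <- divergenceIndex(pa[perm], pb[perm])
  expect_equal(dp$D, divergenceIndex(pa, pb)$D)
})

test_that("peak comparison matrices tabulate shared annual genes", {
  mkRhythm <- function(genes, months, category = "annual")
    data.frame(gene_id = genes, peak_month = months, category = category,
               stringsAsFactors = FALSE)
  a <- mkRhythm(paste0("g", 1:3), c(1, 1, 6))
  b <- mkRhythm(paste0("g", 1:3), c(1, 3, 6))
  pc <- peakComparisonMatrix(a, b)
  expect_equal(pc$counts[1, 1], 1L)
  expect_equal(pc$counts[1, 3], 1L)
  expect_equal(pc$counts[6, 6], 1L)
  expect_equal(sum(pc$counts), 3L)
  # row sums equal species-A peak histogram on shared genes
  expect_equal(unname(rowSums(pc$counts)[c(1, 6)]), c(2L, 1L))

  corr <- data.frame(gene_id = "g1", r = -0.5)
  one <- peakComparisonMatrix(mkRhythm("g1", 4), mkRhythm("g1", 7), corr)
  expect_equal(one$counts[4, 7], 1L)
  expect_true(one$divergent[4, 7])

  onlyB <- mkRhythm("g9", 2)
  expect_error(peakComparisonMatrix(a, onlyB), "annual-rhythmic in both")
})

test_that("monthly profiles enumerate ordered pairs with genus grouping", {
  mk <- function(months) data.frame(gene_id = paste0("g", seq_along(months)),
                                    peak_month = months, category = "annual")
  two <- monthlyProfile(list(Qa = mk(c(1, 2)), Qb = mk(c(1, 2))))
  expect_equal(length(unique(two$pair)), 2)
  expect_equal(nrow(two), 2 * 12)

  four <- monthlyProfile(list(Qa = mk(1), Qb = mk(1),
                              La = mk(1), Lb = mk(1)))
  expect_equal(length(unique(four$pair)), 12)
  expect_setequal(unique(four$grouping), c("intra-genus", "inter-genera"))
  expect_error(monthlyProfile(list(Qa = mk(1))), "at least 2")
})

test_that("across-month comparison separates a winter trough", {
  # identical D everywhere: no significant differences, one letter
  flat <- expand.grid(pair = paste0("p", 1:6), month = 1:12)
  flat$D <- 0.5
  cmpFlat <- compareMonths(flat)
  expect_gt(cmpFlat$friedman_p, 0.99)
  expect_equal(length(unique(cmpFlat$letters)), 1)

  # strong winter trough over 12 blocks
  set.seed(8)
  trough <- expand.grid(pair = paste0("p", 1:12), month = 1:12)
  trough$D <- ifelse(trough$month %in% c(12, 1, 2), 0.1, 0.6) +
    runif(nrow(trough), -0.05, 0.05)
  cmp <- compareMonths(trough)
  expect_lt(cmp$friedman_p, 1e-6)
  winterLetters <- strsplit(cmp$letters[as.character(c(12, 1, 2))], "")
  summerLetters <- strsplit(cmp$letters[as.character(6:8)], "")
  shared <- Reduce(intersect, winterLetters)
  expect_gt(length(shared), 0)
  expect_false(any(shared %in% unlist(summerLetters)))

  twoMonths <- flat[flat$month %in% 1:2, ]
  expect_error(compareMonths(twoMonths), "at least 3")
})

test_that("winter share is the fraction of peaks in the window", {
  expect_equal(winterShare(rep(12, 5)), 1)
  expect_equal(winterShare(rep(1:12, 10)), 0.25)
  expect_equal(winterShare(c(1, 6, 7, 12)), 0.5)
  expect_error(winterShare(integer(0)), "empty")
})
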