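test_that("HWP chi-square matches hand-computed expectations", {
  ## exact Hardy-Weinberg proportions at p = 0.9: chi2 = 0
  g <- handGenotypes(countsRow(810, 180, 10))
  out <- hwpScan(g)
  expect_equal(out$chi2, 0, tolerance = 1e-9)
  expect_equal(out$p, 1)
  expect_identical(out$direction, "none")
  ## counts 850/100/50 at the same allele frequency: expected 810/180/10
  g2 <- handGenotypes(countsRow(850, 100, 50))
  out2 <- hwpScan(g2)
  expect_equal(out2$chi2, 40^2 / 810 + 80^2 / 180 + 40^2 / 10,
               tolerance = 1e-10)
  expect_identical(out2$direction, "het_deficit")
})

test_that("HWP chi-square is invariant to allele-label swap", {
  g <- handGenotypes(countsRow(700, 150, 150))
  gSwap <- handGenotypes(2L - countsRow(700, 150, 150))
  expect_equal(hwpScan(g)$chi2, hwpScan(gSwap)$chi2, tolerance = 1e-12)
})

test_that("monomorphic markers produce chi2 = 0, not NaN", {
  g <- handGenotypes(rbind(rep(0L, 50), rep(2L, 50)))
  out <- hwpScan(g)
  expect_equal(out$chi2, c(0, 0))
  expect_equal(out$p, c(1, 1))
})

test_that("the exact HWE option agrees with chi-square at large counts", {
  g <- handGenotypes(countsRow(850, 100, 50))
  out <- hwpScan(g, exact = TRUE)
  expect_lt(out$pExact, 1e-10)
  g2 <- handGenotypes(countsRow(810, 180, 10))
  expect_gt(hwpScan(g2, exact = TRUE)$pExact, 0.5)
})

test_that("in-deletion markers show a heterozygote deficit; flanks do not", {
  d <- midData()
  hwp <- hwpScan(d$g)
  pop <- d$pop
  inDel <- hwp$pos >= pop@config@deletionStartBp &
    hwp$pos <= pop@config@deletionEndBp
  flagged <- hwp$p < 1e-5 & hwp$direction == "het_deficit"
  ## power varies with the marker's allele frequency; at this sample size
  ## about half the in-deletion markers cross 1e-5, the flanks never do
  expect_gte(mean(flagged[inDel]), 0.5)
  expect_lte(mean(flagged[!inDel]), 0.05)
  relaxed <- hwp$p < 1e-3 & hwp$direction == "het_deficit"
  expect_gte(mean(relaxed[inDel]), 0.8)
  reg <- inferDeletionRegion(hwp)
  expect_false(is.null(reg))
  expect_lt(GenomicRanges::start(reg), pop@config@deletionEndBp)
  expect_gt(GenomicRanges::end(reg), pop@config@deletionStartBp)
})

test_that("intensity rule applies both arms with the ceiling threshold", {
  m <- 139
  n <- 3
  set.seed(61)
  dosage <- matrix(2L, m, n)          # everyone homozygous...
  dosage[1:5, 2] <- 1L                # ...except sample 2 at 5 loci (134)
  dosage[1:2, 1] <- 1L                # sample 1: 137 of 139 homozygous
  g <- handGenotypes(dosage)
  intens <- matrix(0.1, m, n, dimnames = list(rownames(dosages(g)),
                                              colnames(g)))
  intens[, 1] <- -0.3                 # carrier pattern
  intens[, 2] <- -0.3                 # low intensity but 134 < 135 hom
  region <- "23:1-200000"
  calls <- callIntensityCarriers(intens, g, region)
  expect_identical(calls@info$required, 135)      # ceiling(0.97 * 139)
  cc <- carrierCalls(calls)
  expect_identical(as.character(cc[colnames(g)]),
                   c("carrier", "noncarrier", "noncarrier"))
  ## sample 3: all homozygous but positive mean intensity
  expect_identical(as.character(cc[3]), "noncarrier")
})

test_that("lowering the mean threshold never adds carriers", {
  d <- midData()
  intens <- simulateIntensity(d$pop)
  pop <- d$pop
  ## widen the panel: use every marker near the deletion
  reg <- sprintf("23:%d-%d", pop@config@deletionStartBp - 6e5,
                 pop@config@deletionEndBp + 6e5)
  c0 <- carrierIds(callIntensityCarriers(intens, d$g, reg,
                                         meanThreshold = 0))
  cNeg <- carrierIds(callIntensityCarriers(intens, d$g, reg,
                                           meanThreshold = -0.1))
  expect_true(all(cNeg %in% c0))
})

test_that("too few region markers is an error", {
  g <- handGenotypes(matrix(2L, 5, 3))
  intens <- matrix(0, 5, 3, dimnames = list(rownames(dosages(g)),
                                            colnames(g)))
  expect_error(callIntensityCarriers(intens, g, "23:1-10000"), ">= 10")
})

test_that("depth ratios separate carriers and flag uninformative samples", {
  mk <- data.frame(sample = "s1",
                   window_start = seq(1, 1e6, by = 1e4))
  mk$window_end <- mk$window_start + 1e4 - 1
  set.seed(62)
  mk$reads <- rpois(nrow(mk), 1e4)
  inside <- mk$window_start >= 4e5 & mk$window_end <= 6e5
  mk$reads[inside] <- rpois(sum(inside), 5e3)
  calls <- depthRatio(mk, "23:400000-600000")
  expect_identical(as.character(carrierCalls(calls)), "carrier")
  expect_lt(abs(calls@support["s1", "depthRatio"] - 0.5), 0.05)
  mk$reads[!inside] <- 0L
  expect_error(depthRatio(mk, "23:400000-600000"), "s1")
})

test_that("ambiguous band is respected", {
  mk <- data.frame(sample = "s1",
                   window_start = seq(1, 1e6, by = 1e4))
  mk$window_end <- mk$window_start + 1e4 - 1
  mk$reads <- 1000L
  inside <- mk$window_start >= 4e5 & mk$window_end <= 6e5
  mk$reads[inside] <- 780L              # ratio 0.78: between 0.7 and 0.85
  calls <- depthRatio(mk, "23:400000-600000")
  expect_identical(as.character(carrierCalls(calls)), "ambiguous")
})

test_that("concordance cross-tabulates and conditions on carriers", {
  mk <- function(status) {
    calls <- factor(status, levels = c("carrier", "noncarrier",
                                       "ambiguous"))
    names(calls) <- sprintf("a%03d", seq_along(status))
    new("CarrierCallSet", channel = "x", calls = calls,
        support = data.frame(row.names = names(calls)), info = list())
  }
  a <- mk(rep(c("carrier", "noncarrier"), c(47, 153)))
  b <- mk(rep(c("carrier", "noncarrier", "carrier", "noncarrier"),
              c(42, 5, 0, 153)))
  out <- concordance(a, b)
  expect_equal(out$carrierConcordance, 42 / 47)
  expect_equal(out$table["carrier", "carrier"], 42, ignore_attr = TRUE)
  ## identical call sets agree perfectly
  expect_equal(concordance(a, a)$agreement, 1)
  ## ambiguous calls are excluded and counted
  c2 <- mk(c("ambiguous", rep("noncarrier", 199)))
  out2 <- concordance(a, c2)
  expect_identical(out2$nAmbiguous, 1L)
})

test_that("all three evidence channels agree with the simulator truth", {
  pop <- simulatePopulation(SimulationConfig(
    nFounders = 70, nGenerations = 2, nSiresPerGen = 8,
    progenyPerSire = 12, nMarkers = 2000, causativeFreq = 0.09, seed = 1))
  g <- callGenotypes(pop)
  truth <- trueCarrierStatus(pop)
  region <- sprintf("23:%d-%d", pop@config@deletionStartBp,
                    pop@config@deletionEndBp)
  ic <- callIntensityCarriers(simulateIntensity(pop), g, region)
  dep <- simulateDepth(pop, samples = colnames(g))
  dc <- depthRatio(dep, region)
  hc <- assignHaplotypeCarriers(
    lethalscan:::.windowFromHaps(g, pop@tagMarkers, colnames(g)),
    pop@tagAllele)
  for (calls in list(ic, dc, hc)) {
    cc <- carrierCalls(calls)
    agree <- mean((cc == "carrier") == truth[names(cc)])
    expect_gte(agree, 0.9)
  }
  expect_gte(concordance(ic, hc)$agreement, 0.9)
  expect_gte(concordance(dc, hc)$agreement, 0.9)
})
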