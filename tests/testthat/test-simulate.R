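test_that("config validation names the offending field", {
  expect_error(SimulationConfig(causativeFreq = 0.6), "causativeFreq")
  expect_error(SimulationConfig(deletionStartBp = 2e6,
                                deletionEndBp = 1e6), "deletionStartBp")
  expect_error(SimulationConfig(deletionEndBp = 3e7), "deletionEndBp")
  expect_error(SimulationConfig(penetrance = 1.2), "penetrance")
  expect_error(SimulationConfig(nMarkers = 10), "nMarkers")
})

test_that("full penetrance leaves no live deletion homozygote", {
  deadHoms <- 0L
  for (seed in c(1, 2, 3)) {
    pop <- simulatePopulation(smallConfig(causativeFreq = 0.15,
                                          penetrance = 1, seed = seed))
    ind <- pop@individuals
    expect_identical(sum(ind$deletionCopies == 2L & ind$aliveAtBirth), 0L)
    deadHoms <- deadHoms + sum(ind$deletionCopies == 2L & !ind$aliveAtBirth)
  }
  ## dead homozygous conceptuses exist in the record at this frequency
  expect_gt(deadHoms, 0L)
})

test_that("p = 0 gives a deletion-free population at the baseline rate", {
  cfg <- smallConfig(causativeFreq = 0, baselineStillbirth = 0.05,
                     nSiresPerGen = 10, progenyPerSire = 60, seed = 3)
  pop <- simulatePopulation(cfg)
  ind <- pop@individuals
  expect_identical(max(ind$deletionCopies), 0L)
  calves <- ind[ind$generation >= 1, ]
  rate <- mean(!calves$aliveAtBirth)
  se <- sqrt(0.05 * 0.95 / nrow(calves))
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("Mendelian transmission is fair over many meioses", {
  ## 1 sire x 1 dam founders, 8000 progeny: each parental haplotype should
  ## be transmitted with frequency 0.5 within 3 binomial SE
  cfg <- SimulationConfig(nFounders = 2, nGenerations = 1,
                          nSiresPerGen = 1, progenyPerSire = 8000,
                          nMarkers = 50, causativeFreq = 0, seed = 11)
  pop <- simulatePopulation(cfg)
  founders <- which(pop@individuals$generation == 0)
  sire <- founders[pop@individuals$sex[founders] == "M"]
  calves <- which(pop@individuals$generation == 1)
  ## at sire-heterozygous markers, paternal gamete allele frequency ~ 0.5
  het <- which(pop@hap1[, sire] != pop@hap2[, sire])
  expect_gt(length(het), 5)
  n <- length(calves)
  se3 <- 3 * sqrt(0.25 / n)
  for (m in het[1:5]) {
    fr <- mean(pop@hap1[m, calves] == pop@hap1[m, sire])
    expect_lt(abs(fr - 0.5), se3 + 1e-9)
  }
})

test_that("identical seeds give bit-identical populations and layers", {
  cfg <- smallConfig(seed = 42)
  p1 <- simulatePopulation(cfg)
  p2 <- simulatePopulation(cfg)
  expect_identical(p1@hap1, p2@hap1)
  expect_identical(p1@individuals, p2@individuals)
  expect_identical(dosages(callGenotypes(p1)), dosages(callGenotypes(p2)))
  expect_identical(simulateIntensity(p1), simulateIntensity(p2))
  expect_identical(simulateDepth(p1), simulateDepth(p2))
  expect_identical(simulateRecordsAndDrp(p1), simulateRecordsAndDrp(p2))
})

test_that("hemizygote masking calls carriers homozygous inside the deletion", {
  ## no calling error: carriers are homozygous at every in-deletion marker
  pop <- simulatePopulation(smallConfig(genotypeError = 0,
                                        causativeFreq = 0.15, seed = 5))
  g <- callGenotypes(pop)
  ind <- pop@individuals
  carriers <- ind$id[ind$deletionCopies == 1L & ind$aliveAtBirth]
  nonc <- ind$id[ind$deletionCopies == 0L & ind$aliveAtBirth]
  mk <- markerInfo(g)
  inDel <- mk$pos >= pop@config@deletionStartBp &
    mk$pos <= pop@config@deletionEndBp
  D <- dosages(g)
  expect_true(all(D[inDel, carriers] %in% c(0L, 2L)))
  ## noncarrier calls equal true dosages everywhere at zero error
  live <- match(nonc, ind$id)
  expect_identical(D[, nonc],
                   pop@hap1[, live] + pop@hap2[, live])
})

test_that("per-call error perturbs homozygous calls at the stated rate", {
  pop <- simulatePopulation(smallConfig(genotypeError = 0.03,
                                        causativeFreq = 0.15,
                                        nMarkers = 400, seed = 6))
  g <- callGenotypes(pop)
  ind <- pop@individuals
  carriers <- ind$id[ind$deletionCopies == 1L & ind$aliveAtBirth]
  mk <- markerInfo(g)
  inDel <- mk$pos >= pop@config@deletionStartBp &
    mk$pos <= pop@config@deletionEndBp
  hom <- dosages(g)[inDel, carriers] %in% c(0L, 2L)
  ## P(homozygous call | carrier, in-deletion) = 1 - e; binomial tolerance
  nCalls <- sum(inDel) * length(carriers)
  expect_gt(nCalls, 200)
  expect_lt(abs(mean(hom) - 0.97), 4 * sqrt(0.97 * 0.03 / nCalls))
})

test_that("intensity layer is exact at zero noise and shifted for carriers", {
  pop <- simulatePopulation(smallConfig(intensitySd = 0,
                                        causativeFreq = 0.15, seed = 8))
  x <- simulateIntensity(pop)
  ind <- pop@individuals
  live <- ind[ind$aliveAtBirth, ]
  mk <- pop@markers
  inDel <- mk$pos >= pop@config@deletionStartBp &
    mk$pos <= pop@config@deletionEndBp
  carriers <- live$id[live$deletionCopies == 1L]
  nonc <- live$id[live$deletionCopies == 0L]
  expect_true(all(x[inDel, carriers] == pop@config@intensityMeanCarrier))
  expect_true(all(x[, nonc] == 0))
  expect_true(all(x[!inDel, carriers] == 0))
})

test_that("carrier mean in-deletion intensity is negative at defaults", {
  pop <- simulatePopulation(smallConfig(causativeFreq = 0.2,
                                        penetrance = 0, nMarkers = 400,
                                        seed = 9))
  x <- simulateIntensity(pop)
  ind <- pop@individuals
  carriers <- ind$id[ind$deletionCopies == 1L & ind$aliveAtBirth]
  mk <- pop@markers
  inDel <- mk$pos >= pop@config@deletionStartBp &
    mk$pos <= pop@config@deletionEndBp
  expect_gt(length(carriers), 30)
  expect_gte(mean(colMeans(x[inDel, carriers]) < 0), 0.99)
})

test_that("depth is Poisson with halved in-deletion rate for carriers", {
  pop <- simulatePopulation(smallConfig(causativeFreq = 0.15, seed = 10))
  ind <- pop@individuals
  carr <- ind$id[ind$deletionCopies == 1L & ind$aliveAtBirth][1:5]
  nonc <- ind$id[ind$deletionCopies == 0L & ind$aliveAtBirth][1:5]
  dep <- simulateDepth(pop, samples = c(carr, nonc))
  cfg <- pop@config
  mid <- (dep$window_start + dep$window_end) / 2
  inside <- mid >= cfg@deletionStartBp & mid <= cfg@deletionEndBp
  for (s in carr) {
    r <- mean(dep$reads[dep$sample == s & inside]) /
      mean(dep$reads[dep$sample == s & !inside])
    expect_lt(abs(r - 0.5), 0.05)
  }
  for (s in nonc) {
    r <- mean(dep$reads[dep$sample == s & inside]) /
      mean(dep$reads[dep$sample == s & !inside])
    expect_lt(abs(r - 1), 0.05)
  }
  ## Poisson moment check off-region: variance ~ mean across windows
  s <- nonc[1]
  reads <- dep$reads[dep$sample == s & !inside]
  expect_lt(abs(var(reads) / mean(reads) - 1), 0.15)
  ## reproducible under the same seed
  expect_identical(dep, simulateDepth(pop, samples = c(carr, nonc)))
})

test_that("DRPs are unaffected by carrier status when p = 0", {
  pop <- simulatePopulation(smallConfig(causativeFreq = 0, seed = 12))
  drp <- simulateRecordsAndDrp(pop)$drp
  expect_true(all(drp$reliability > 0 & drp$reliability <= 1))
  ## delta term vanishes: DRP = bv + noise; regression of drp on bv ~ 1
  ind <- pop@individuals
  bv <- ind$bv[match(drp$id, ind$id)]
  b <- coef(lm(drp$drp ~ bv))[2]
  expect_lt(abs(b - 1), 0.1)
})

test_that("dead conceptuses enter the calving table but are not genotyped", {
  pop <- simulatePopulation(smallConfig(causativeFreq = 0.15, seed = 13))
  g <- callGenotypes(pop)
  rec <- simulateRecordsAndDrp(pop)
  ind <- pop@individuals
  dead <- ind$id[!ind$aliveAtBirth]
  expect_gt(length(dead), 0)
  expect_true(all(dead %in% rec$calving$calf))
  expect_false(any(dead %in% colnames(g)))
})
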