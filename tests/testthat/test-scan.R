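test_that("Bonferroni line matches the standard values", {
  expect_equal(round(bonferroniThreshold(0.05, 8938927), 2), 8.25)
  expect_equal(round(bonferroniThreshold(0.05, 1), 2), 1.30)
  expect_equal(bonferroniThreshold(1, 1), 0)
})

test_that("monomorphic markers are skipped with a reason", {
  d <- midData()
  mono <- handGenotypes(rbind(rep(1L, 40), rep(0L, 40),
                              matrix(rbinom(40, 2, 0.4), 1)))
  set.seed(1)
  sire <- rep(sprintf("S%02d", 1:8), each = 5)
  ped <- data.frame(id = colnames(mono),
                    sire = sire, dam = NA, stringsAsFactors = FALSE)
  ped <- rbind(ped, data.frame(id = unique(sire), sire = NA, dam = NA))
  pheno <- data.frame(id = colnames(mono), drp = rnorm(40),
                      reliability = 0.8)
  sc <- scanSireModel(mono, pheno, ped)
  tb <- as.data.frame(sc)
  expect_identical(tb$note,
                   c("skipped_monomorphic", "skipped_monomorphic", "ok"))
  expect_true(all(is.na(tb$p[1:2])))
  expect_identical(sc@nTests, 1L)
})

test_that("allele-coding flip negates the effect and keeps p", {
  d <- midData()
  sub <- markerInfo(d$g)$id[seq(10, 100, by = 30)]
  gSub <- d$g[markerInfo(d$g)$id %in% sub, ]
  sc1 <- scanSireModel(gSub, d$pheno, d$ped)
  flipped <- GenotypeData(markerInfo(gSub)[, 1:5],
                          2L - dosages(gSub))
  colnames(flipped) <- colnames(gSub)
  sc2 <- scanSireModel(flipped, d$pheno, d$ped)
  t1 <- as.data.frame(sc1)
  t2 <- as.data.frame(sc2)
  expect_equal(t1$beta, -t2$beta, tolerance = 1e-6)
  expect_equal(t1$p, t2$p, tolerance = 1e-6)
})

test_that("scan results are invariant to marker order", {
  d <- midData()
  ids <- markerInfo(d$g)$id[c(5, 50, 200)]
  gSub <- d$g[markerInfo(d$g)$id %in% ids, ]
  sc <- scanSireModel(gSub, d$pheno, d$ped)
  ## GenotypeData sorts by position internally, so feed a reversed copy
  mk <- markerInfo(gSub)
  rev <- GenotypeData(mk[3:1, 1:5], dosages(gSub)[3:1, ],
                      hapMatrix(gSub, 1)[3:1, ], hapMatrix(gSub, 2)[3:1, ])
  colnames(rev) <- colnames(gSub)
  sc2 <- scanSireModel(rev, d$pheno, d$ped)
  expect_equal(as.data.frame(sc)$p, as.data.frame(sc2)$p,
               tolerance = 1e-10)
})

test_that("phenotyped animals without a pedigree sire are rejected", {
  d <- midData()
  badPed <- d$ped
  badPed$sire[match(d$pheno$id[1], badPed$id)] <- NA
  expect_error(scanSireModel(d$g, d$pheno, badPed), "without a sire")
})

test_that("the planted deletion wins the sire scan with a negative effect", {
  d <- midData()
  gs <- filterMarkers(d$g, 0.01, hwpPMin = 0)
  sc <- scanSireModel(gs, d$pheno, d$ped)
  tb <- as.data.frame(sc)
  peak <- tb[which.min(tb$p), ]
  expect_true(peak$id %in% d$tagIds)
  ## deletion allele (alt at tag markers) reduces the survival DRP
  expect_lt(peak$beta, 0)
  expect_gt(peak$mlog10p, bonferroniThreshold(0.05, sc@nTests))
})

test_that("fast mode agrees with per-marker re-estimation near the peak", {
  d <- midData()
  gs <- filterMarkers(d$g, 0.01, hwpPMin = 0)
  sub <- gs[seq(1, nrow(gs), by = 40), ]
  exact <- as.data.frame(scanSireModel(sub, d$pheno, d$ped))
  fast <- as.data.frame(scanSireModel(sub, d$pheno, d$ped,
                                      reestimate = FALSE))
  expect_equal(exact$beta, fast$beta, tolerance = 0.02)
  ok <- exact$mlog10p > 1
  expect_equal(exact$mlog10p[ok], fast$mlog10p[ok], tolerance = 0.15)
})

test_that("animal model with identity A reduces to weighted regression", {
  set.seed(71)
  n <- 80
  dosage <- matrix(rbinom(4 * n, 2, 0.4), 4)
  storage.mode(dosage) <- "integer"
  g <- handGenotypes(dosage)
  ids <- colnames(g)
  pheno <- data.frame(id = ids, drp = rnorm(n), reliability = 0.5)
  A <- diag(n)
  dimnames(A) <- list(ids, ids)
  sc <- scanAnimalModel(g, pheno, A)
  tb <- as.data.frame(sc)
  for (j in 1:4) {
    lmf <- lm(pheno$drp ~ dosage[j, ])
    expect_equal(tb$beta[j], unname(coef(lmf)[2]), tolerance = 1e-6)
    expect_equal(tb$se[j], unname(coef(summary(lmf))[2, 2]),
                 tolerance = 1e-3)
  }
})

test_that("an all-zero cofactor leaves the animal model unchanged", {
  set.seed(72)
  n <- 60
  dosage <- matrix(rbinom(3 * n, 2, 0.4), 3)
  storage.mode(dosage) <- "integer"
  g <- handGenotypes(dosage)
  ids <- colnames(g)
  pheno <- data.frame(id = ids, drp = rnorm(n), reliability = 0.7)
  A <- diag(n); dimnames(A) <- list(ids, ids)
  plain <- as.data.frame(scanAnimalModel(g, pheno, A))
  cof <- stats::setNames(rep(0, n), ids)
  expect_message(
    withCof <- as.data.frame(cofactorScan(g, pheno, A, cof)),
    "constant cofactor")
  expect_equal(plain$p, withCof$p, tolerance = 1e-10)
})

test_that("a marker collinear with the cofactor is flagged not estimable", {
  set.seed(73)
  n <- 60
  x <- rbinom(n, 2, 0.4)
  dosage <- rbind(as.integer(x), matrix(rbinom(2 * n, 2, 0.4), 2))
  storage.mode(dosage) <- "integer"
  g <- handGenotypes(dosage)
  ids <- colnames(g)
  pheno <- data.frame(id = ids, drp = rnorm(n), reliability = 0.7)
  A <- diag(n); dimnames(A) <- list(ids, ids)
  cof <- stats::setNames(x, ids)
  tb <- as.data.frame(cofactorScan(g, pheno, A, cof))
  expect_identical(tb$note[1], "not_estimable")
  expect_true(is.na(tb$p[1]))
  expect_identical(tb$note[2:3], c("ok", "ok"))
})

test_that("top-marker selection ranks by p with position tie-break", {
  tb <- data.frame(id = c("a", "b", "c", "d"), pos = c(40, 10, 30, 20),
                   maf = 0.1, beta = 0, se = 1,
                   p = c(0.5, 0.01, 0.01, NA), mlog10p = 1, note = "ok")
  sc <- new("ScanResult", table = tb, model = "sire", nTests = 3L)
  expect_identical(topMarkers(sc, 2), c("b", "c"))  # map order after pick
})

test_that("random haplotype model recovers the planted tag haplotype", {
  d <- midData()
  gs <- filterMarkers(d$g, 0.01, hwpPMin = 0)
  sc <- scanSireModel(gs, d$pheno, d$ped)
  top <- topMarkers(sc, 10)
  expect_true(all(top %in% d$tagIds))
  set.seed(1)
  sub <- sort(sample(d$pheno$id, 500))
  ph <- d$pheno[d$pheno$id %in% sub, ]
  A <- buildA(prunePedigree(d$ped, sub))
  rhm <- fitRhm(gs, ph, A, top)
  expect_identical(rhm$hapQtl, d$pop@tagAllele)
  expect_lt(rhm$lrt$p, 0.01)
  expect_lt(rhm$effects$blup[1], 0)
  ## window over 10 biallelic SNPs: at most 1024 distinct alleles
  expect_lte(length(rhm$effects$allele), haplotypeSpace(10))
  ## cofactor re-scan: the tag haplotype explains the QTL
  ti <- rhm$effects$allele[1]
  win <- lethalscan:::.windowFromHaps(gs, match(top, markerInfo(gs)$id),
                                      colnames(gs))
  cof <- (win@hap1Allele == match(ti, win@alleles)) +
    (win@hap2Allele == match(ti, win@alleles))
  names(cof) <- names(win@hap1Allele)
  cs <- cofactorScan(gs, ph, A, cof)
  ct <- as.data.frame(cs)
  sTab <- as.data.frame(sc)
  wasSig <- sTab$id[!is.na(sTab$mlog10p) &
                      sTab$mlog10p > bonferroniThreshold(0.05, sc@nTests)]
  expect_true(all(ct$mlog10p[ct$id %in% wasSig] <
                    bonferroniThreshold(0.05, cs@nTests), na.rm = TRUE))
})

test_that("RHM finds no haplotype variance on a null trait", {
  d <- midData()
  set.seed(2)
  sub <- sort(sample(d$pheno$id, 300))
  phNull <- data.frame(id = sub, drp = rnorm(300), reliability = 0.8)
  A <- buildA(prunePedigree(d$ped, sub))
  gs <- filterMarkers(d$g, 0.01, hwpPMin = 0)
  rhm <- fitRhm(gs, phNull, A, d$tagIds)
  expect_gt(rhm$lrt$p, 0.05)
})
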