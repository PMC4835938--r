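## Single-marker association scans, Bonferroni thresholding, cofactor
## re-scan and the random haplotype model.

.preparePheno <- function(g, pheno) {
  stopifnot(all(c("id", "drp", "reliability") %in% names(pheno)))
  ids <- intersect(pheno$id, colnames(g))
  if (!length(ids)) stop("no phenotyped animal has genotypes")
  ph <- pheno[match(ids, pheno$id), , drop = FALSE]
  list(ids = ids, y = ph$drp, w = drpWeight(ph$reliability))
}

## Shared per-marker loop over a prepared REML structure.
.scanLoop <- function(g, prep, ids, reestimate, model, extraAliased = NULL) {
  mk <- markerInfo(g)
  D <- dosages(g)[, ids, drop = FALSE]
  lambdaFix <- NULL
  if (!reestimate) {
    nullFit <- .remlSolve(prep)
    if (!nullFit$ok) stop("null model not estimable")
    lambdaFix <- nullFit$theta
  }
  n <- length(ids)
  res <- data.frame(id = mk$id, pos = mk$pos, maf = mk$maf,
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    mlog10p = NA_real_, note = "ok",
                    stringsAsFactors = FALSE)
  nTests <- 0L
  for (j in seq_len(nrow(mk))) {
    x <- as.numeric(D[j, ])
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    if (stats::var(x) < 1e-12) {
      res$note[j] <- "skipped_monomorphic"
      next
    }
    Xadd <- matrix(x, n, 1, dimnames = list(NULL, "dosage"))
    fit <- .remlSolve(prep, Xadd = Xadd, lambdaLog = lambdaFix)
    if (!fit$ok) {
      res$note[j] <- "not_estimable"
      next
    }
    k <- fit$p                    # marker coefficient is the last column
    b <- fit$beta[k]
    s <- sqrt(max(fit$covBeta[k, k], 0))
    z <- if (s > 0) b / s else 0
    res$beta[j] <- b
    res$se[j] <- s
    res$p[j] <- 2 * stats::pnorm(-abs(z))
    res$mlog10p[j] <- .mlog10pNorm(z)
    nTests <- nTests + 1L
  }
  new("ScanResult", table = res, model = model, nTests = nTests)
}

#' Whole-chromosome scan with the half-sib sire model
#'
#' Fits, for each marker, \eqn{y = \mu + b x + s + e} with a random iid
#' half-sib family effect \eqn{s \sim N(0, \sigma_s^2)} and residuals
#' weighted by the DRP reliabilities (\eqn{e \sim N(0, W^{-1}\sigma_e^2)}).
#' Variance components are re-estimated for every marker by default; with
#' \code{reestimate = FALSE} they are profiled once under the no-marker
#' null and held fixed (a faster score-like mode, flagged in the result's
#' model label). Monomorphic markers are skipped with a note.
#'
#' @param g [GenotypeData-class] for the phenotyped animals.
#' @param pheno data.frame with id, drp, reliability.
#' @param pedigree data.frame (id, sire, dam); every phenotyped animal must
#'   have a recorded sire.
#' @param reestimate Re-estimate variance components per marker.
#' @return A [ScanResult-class].
#' @export
scanSireModel <- function(g, pheno, pedigree, reestimate = TRUE) {
  pp <- .preparePheno(g, pheno)
  sire <- pedigree$sire[match(pp$ids, pedigree$id)]
  if (anyNA(sire))
    stop("phenotyped animal(s) without a sire in the pedigree: ",
         paste(utils::head(pp$ids[is.na(sire)], 5), collapse = ", "))
  Z <- stats::model.matrix(~ 0 + factor(sire))
  X0 <- matrix(1, length(pp$y), 1, dimnames = list(NULL, "(Intercept)"))
  prep <- .remlPrep(pp$y, X0, random = list(sire = list(Z = Z)),
                    weights = pp$w)
  .scanLoop(g, prep, pp$ids, reestimate,
            if (reestimate) "sire" else "sire (fast)")
}

#' Region scan with the pedigree animal model
#'
#' As [scanSireModel()] but with a polygenic random effect
#' \eqn{u \sim N(0, A\sigma_u^2)} structured by the additive relationship
#' matrix, i.e. a single-locus regression of the phenotype on allele dosage
#' for each marker separately.
#'
#' @inheritParams scanSireModel
#' @param A Additive relationship matrix covering the phenotyped ids (see
#'   [buildA()]).
#' @param cofactor Optional named numeric vector (per animal, in 0/1/2) of
#'   a haplotype dosage added as a fixed regression; markers collinear with
#'   the cofactor are reported non-estimable.
#' @return A [ScanResult-class].
#' @export
scanAnimalModel <- function(g, pheno, A, reestimate = TRUE,
                            cofactor = NULL) {
  pp <- .preparePheno(g, pheno)
  if (!all(pp$ids %in% rownames(A)))
    stop("relationship matrix does not cover all phenotyped animals")
  Asub <- A[pp$ids, pp$ids]
  X0 <- matrix(1, length(pp$y), 1, dimnames = list(NULL, "(Intercept)"))
  model <- "animal"
  if (!is.null(cofactor)) {
    if (is.null(names(cofactor))) stop("cofactor must be named by animal")
    if (!all(cofactor %in% 0:2)) stop("cofactor dosages must be 0, 1 or 2")
    cf <- as.numeric(cofactor[pp$ids])
    if (stats::var(cf) > 0) {
      X0 <- cbind(X0, cofactor = cf)
    } else {
      message("constant cofactor dropped; scan equals the plain animal model")
    }
    model <- "animal+cofactor"
  }
  prep <- .remlPrep(pp$y, X0,
                    random = list(polygenic = list(Z = NULL, K = Asub)),
                    weights = pp$w)
  .scanLoop(g, prep, pp$ids, reestimate,
            if (reestimate) model else paste(model, "(fast)"))
}

#' Animal-model scan with a haplotype cofactor
#'
#' Convenience wrapper around [scanAnimalModel()] that adds the designated
#' haplotype count as a fixed regression; on a single-QTL chromosome whose
#' QTL the cofactor tags, no residual association should remain above the
#' Bonferroni line.
#'
#' @inheritParams scanAnimalModel
#' @param cofactorDosage Named per-animal count (0/1/2) of the designated
#'   haplotype.
#' @export
cofactorScan <- function(g, pheno, A, cofactorDosage, reestimate = TRUE) {
  scanAnimalModel(g, pheno, A, reestimate = reestimate,
                  cofactor = cofactorDosage)
}

#' Bonferroni genome-wide significance line
#'
#' @param alpha Nominal family-wise error rate.
#' @param nTests Number of simultaneous tests.
#' @return \eqn{-\log_{10}(\alpha / n)}; summaries print it to 2 decimals.
#' @examples
#' round(bonferroniThreshold(0.05, 8938927), 2)  # 8.25
#' @export
bonferroniThreshold <- function(alpha, nTests) {
  stopifnot(alpha > 0, alpha <= 1, nTests >= 1)
  -log10(alpha / nTests)
}

#' Pick the top markers of a scan for haplotype construction
#'
#' Ranks by p ascending with ties broken by position ascending and returns
#' the marker ids in map order.
#'
#' @param scan A [ScanResult-class].
#' @param k Number of markers (default 10).
#' @export
topMarkers <- function(scan, k = 10) {
  tb <- scan@table
  tb <- tb[!is.na(tb$p), , drop = FALSE]
  tb <- tb[order(tb$p, tb$pos), , drop = FALSE]
  sel <- utils::head(tb, k)
  sel$id[order(sel$pos)]
}

#' Random haplotype model for a marker window
#'
#' Enumerates the haplotype alleles of a phased window and fits
#' \eqn{y = \mu + q_{h1} + q_{h2} + u + e} where the two window haplotypes
#' carried by each animal are iid random effects sharing one variance
#' \eqn{\sigma_h^2} (each animal contributes two incidence entries), on top
#' of the pedigree polygenic effect. Significance is a likelihood-ratio
#' test against the no-haplotype null (chi-square, 1 df). The haplotype
#' allele with the most negative BLUP is designated the putative
#' QTL-carrying haplotype.
#'
#' @inheritParams scanAnimalModel
#' @param windowMarkers Character ids of the (phased) window markers.
#' @return list with elements \code{fit}, \code{null}, \code{lrt}
#'   (statistic, p), \code{effects} (allele, frequency, BLUP) and
#'   \code{hapQtl} (the designated allele string).
#' @export
fitRhm <- function(g, pheno, A, windowMarkers) {
  if (!isPhased(g)) stop("random haplotype model requires phased genotypes")
  pp <- .preparePheno(g, pheno)
  mk <- markerInfo(g)
  idx <- match(windowMarkers, mk$id)
  if (anyNA(idx)) stop("unknown window marker id(s)")
  win <- .windowFromHaps(g, sort(idx), pp$ids)
  H <- length(win@alleles)
  n <- length(pp$ids)
  Z <- matrix(0, n, H, dimnames = list(NULL, win@alleles))
  Z[cbind(seq_len(n), win@hap1Allele)] <- Z[cbind(seq_len(n),
                                                  win@hap1Allele)] + 1
  Z[cbind(seq_len(n), win@hap2Allele)] <- Z[cbind(seq_len(n),
                                                  win@hap2Allele)] + 1
  Asub <- A[pp$ids, pp$ids]
  X0 <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))

  full <- remlFit(pp$y, X0,
                  random = list(haplotype = list(Z = Z),
                                polygenic = list(Z = NULL, K = Asub)),
                  weights = pp$w, blup = TRUE)
  null <- remlFit(pp$y, X0,
                  random = list(polygenic = list(Z = NULL, K = Asub)),
                  weights = pp$w)
  test <- lrt(full, null)
  q <- full@blup$haplotype
  effects <- data.frame(allele = win@alleles, freq = win@freq,
                        blup = as.numeric(q[win@alleles]),
                        stringsAsFactors = FALSE)
  effects <- effects[order(effects$blup), , drop = FALSE]
  list(fit = full, null = null, lrt = test, effects = effects,
       hapQtl = effects$allele[1])
}
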