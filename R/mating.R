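## Sire x maternal-grandsire mating-type analysis of stillbirth.

#' Classify matings by sire and maternal-grandsire carrier status
#'
#' Type I: noncarrier sire x daughter of noncarrier MGS; II: noncarrier
#' sire x daughter of carrier MGS; III: carrier sire x daughter of
#' noncarrier MGS; IV: carrier sire x daughter of carrier MGS.
#'
#' @param sireCarrier,mgsCarrier Logical vectors.
#' @return Factor with levels I, II, III, IV.
#' @examples
#' classifyMating(c(FALSE, TRUE), c(FALSE, TRUE))  # I, IV
#' @export
classifyMating <- function(sireCarrier, mgsCarrier) {
  stopifnot(is.logical(sireCarrier), is.logical(mgsCarrier))
  code <- 1L + 2L * as.integer(sireCarrier) + as.integer(mgsCarrier)
  factor(c("I", "II", "III", "IV")[code], levels = c("I", "II", "III", "IV"))
}

#' Expected homozygous-conceptus fraction by mating type
#'
#' Under Hardy-Weinberg proportions the expected fraction of conceptuses
#' homozygous for the causative allele is 0 for types I and II,
#' \eqn{p/(4(1+p))} for type III and \eqn{(1+p)/(4(2+p))} for type IV,
#' where \eqn{p} is the causative allele frequency; the type-IV fraction
#' tends to 1/8 (12.5\%) as \eqn{p \to 0}.
#'
#' @param matingType "I", "II", "III" or "IV" (vectorized, factors
#'   accepted).
#' @param p Causative allele frequency in [0, 1).
#' @return Expected homozygote fraction(s).
#' @examples
#' expectedHomozygoteFraction("IV", 0)      # 0.125
#' expectedHomozygoteFraction("III", 0.043) # ~0.0103
#' @export
expectedHomozygoteFraction <- function(matingType, p) {
  stopifnot(p >= 0, p < 1)
  mt <- as.character(matingType)
  if (!all(mt %in% c("I", "II", "III", "IV")))
    stop("matingType must be I, II, III or IV")
  unname(vapply(mt, function(t) switch(t,
    I = 0, II = 0,
    III = p / (4 * (1 + p)),
    IV = (1 + p) / (4 * (2 + p))), 0))
}

#' Build mating records from a calving table and carrier calls
#'
#' Joins each calving record with the carrier status of the sire and of
#' the maternal grandsire and codes the outcome as 1 = stillborn (the
#' recording convention is 1 = alive 24 h after birth; the conversion is
#' explicit here). Records whose sire or MGS lacks a carrier call are
#' dropped with a message.
#'
#' @param calving data.frame with calf, sire, dam, mgs, parity, insem_ym,
#'   alive (1 = survived).
#' @param carrierStatus Named logical vector (or [CarrierCallSet-class])
#'   giving carrier status per bull; ambiguous calls count as missing.
#' @return data.frame of mating records: calf, sire, mgs, matingType,
#'   parity, insem_ym, stillborn.
#' @export
buildMatingRecords <- function(calving, carrierStatus) {
  if (is(carrierStatus, "CarrierCallSet")) {
    cs <- carrierStatus@calls
    carrierStatus <- stats::setNames(cs == "carrier", names(cs))
    carrierStatus[cs == "ambiguous"] <- NA
  }
  sc <- carrierStatus[calving$sire]
  mc <- carrierStatus[calving$mgs]
  ok <- !is.na(sc) & !is.na(mc) & !is.na(calving$mgs)
  if (any(!ok))
    message(sum(!ok), " record(s) dropped (no carrier call for sire/MGS)")
  cv <- calving[ok, , drop = FALSE]
  data.frame(calf = cv$calf, sire = cv$sire, mgs = cv$mgs,
             matingType = classifyMating(unname(sc[ok]), unname(mc[ok])),
             parity = cv$parity, insem_ym = cv$insem_ym,
             stillborn = 1L - cv$alive, stringsAsFactors = FALSE)
}

#' Mixed-model test of mating-type effects on stillbirth
#'
#' Linear mixed model on the 0/1 stillbirth outcome (the routine-evaluation
#' convention; a logistic variant is available for sensitivity analysis):
#' fixed parity, insemination month-year and mating type; random maternal
#' grandsire with covariance \eqn{\sigma_g^2 A_s} from the sire pedigree.
#' Returns contrasts of each mating type against type I; a type with no
#' records is reported absent.
#'
#' @param records Mating records from [buildMatingRecords()].
#' @param pedigree Optional pedigree (id, sire, dam) from which the MGS
#'   relationship matrix is built; identity covariance when NULL.
#' @param logistic Fit a logistic GLMM-free fixed-effect approximation
#'   instead (glm with MGS ignored); sensitivity only.
#' @return list with \code{fit} ([RemlFit-class] or glm), \code{contrasts}
#'   data.frame (matingType, estimate, se, z, p) and \code{model} label.
#' @export
fitMatingModel <- function(records, pedigree = NULL, logistic = FALSE) {
  stopifnot(all(c("matingType", "parity", "insem_ym", "stillborn", "mgs")
                %in% names(records)))
  records$matingType <- factor(as.character(records$matingType),
                               levels = c("I", "II", "III", "IV"))
  present <- levels(droplevels(records$matingType))
  mtF <- droplevels(records$matingType)
  parityF <- factor(pmin(as.integer(records$parity), 5L))
  ymF <- factor(records$insem_ym)
  ## single-level fixed factors carry no contrast and are dropped
  df <- data.frame(stillborn = records$stillborn, parityF = parityF,
                   ymF = ymF, matingType = mtF)
  keep <- c("stillborn",
            names(df)[-1][vapply(df[-1], nlevels, 0L) >= 2L])
  df <- df[, keep, drop = FALSE]
  terms <- setdiff(keep, "stillborn")
  form <- if (length(terms))
    stats::reformulate(terms, response = "stillborn") else
      stillborn ~ 1

  if (logistic) {
    fit <- stats::glm(form, family = stats::binomial(), data = df)
    co <- summary(fit)$coefficients
    rows <- grep("^matingType", rownames(co))
    contrasts <- data.frame(
      matingType = sub("matingType", "", rownames(co)[rows]),
      estimate = co[rows, 1], se = co[rows, 2], z = co[rows, 3],
      p = co[rows, 4], row.names = NULL)
    return(list(fit = fit, contrasts = contrasts, model = "logistic"))
  }

  X <- stats::model.matrix(form, df)
  ## drop aliased non-focal columns (e.g. a month-year with one record)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    focal <- grep("^matingType", colnames(X))
    drop <- setdiff(drop, focal)
    if (length(drop)) X <- X[, -drop, drop = FALSE]
  }
  mgsF <- factor(records$mgs)
  Z <- stats::model.matrix(~ 0 + mgsF)
  colnames(Z) <- levels(mgsF)
  K <- NULL
  if (!is.null(pedigree)) {
    As <- buildA(prunePedigree(pedigree, levels(mgsF)))
    K <- As[levels(mgsF), levels(mgsF)]
  }
  fit <- remlFit(records$stillborn, X,
                 random = list(mgs = list(Z = Z, K = K)))
  nm <- paste0("matingType", setdiff(present, "I"))
  nm <- intersect(nm, names(fit@beta))
  z <- fit@beta[nm] / fit@se[nm]
  contrasts <- data.frame(
    matingType = sub("matingType", "", nm),
    estimate = unname(fit@beta[nm]), se = unname(fit@se[nm]),
    z = unname(z), p = unname(2 * stats::pnorm(-abs(z))), row.names = NULL)
  list(fit = fit, contrasts = contrasts, model = "linear")
}

#' Stillbirth rate table by stratum and mating type
#'
#' Counts and survival percentages per population stratum and mating type
#' with row and column totals; every record is counted exactly once.
#'
#' @param records Mating records (from [buildMatingRecords()]); an optional
#'   \code{stratum} column defines the rows (a single stratum "all"
#'   otherwise).
#' @return data.frame with, per stratum and per mating type, N and
#'   Survival (\%), plus Total columns and a Total row.
#' @export
stillbirthRateTable <- function(records) {
  if (is.null(records$stratum)) records$stratum <- "all"
  mt <- factor(as.character(records$matingType),
               levels = c("I", "II", "III", "IV"))
  st <- factor(records$stratum, levels = unique(records$stratum))
  N <- table(st, mt)
  surv <- tapply(1 - records$stillborn, list(st, mt), mean) * 100
  out <- data.frame(stratum = rownames(N), stringsAsFactors = FALSE)
  for (t in levels(mt)) {
    out[[paste0("N_", t)]] <- as.integer(N[, t])
    out[[paste0("Survival_", t)]] <- round(surv[, t], 1)
  }
  out$N_Total <- as.integer(rowSums(N))
  out$Survival_Total <- round(
    tapply(1 - records$stillborn, st, mean) * 100, 1)
  total <- data.frame(stratum = "Total", stringsAsFactors = FALSE)
  for (t in levels(mt)) {
    total[[paste0("N_", t)]] <- sum(out[[paste0("N_", t)]])
    total[[paste0("Survival_", t)]] <-
      round(mean((1 - records$stillborn)[mt == t]) * 100, 1)
  }
  total$N_Total <- sum(out$N_Total)
  total$Survival_Total <- round(mean(1 - records$stillborn) * 100, 1)
  rbind(out, total)
}
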