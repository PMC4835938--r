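## Shared fixtures. Populations are memoized so several test files can
## reuse the same mid-sized simulation without re-running it.

.fixtureEnv <- new.env(parent = emptyenv())

memoFixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureEnv))
    assign(name, builder(), envir = .fixtureEnv)
  get(name, envir = .fixtureEnv)
}

## quick config for cheap unit tests
smallConfig <- function(...) {
  args <- utils::modifyList(
    list(nFounders = 80, nGenerations = 2, nSiresPerGen = 8,
         progenyPerSire = 15, nMarkers = 120, seed = 101), list(...))
  do.call(SimulationConfig, args)
}

## mid-sized planted-deletion population shared across scan/lethal tests
midPop <- function() memoFixture("midPop", function() {
  simulatePopulation(SimulationConfig(
    nFounders = 600, nGenerations = 2, nSiresPerGen = 30,
    progenyPerSire = 40, nMarkers = 400, causativeFreq = 0.06, seed = 7))
})

midData <- function() memoFixture("midData", function() {
  pop <- midPop()
  g <- callGenotypes(pop)
  rec <- simulateRecordsAndDrp(pop)
  list(pop = pop, g = g,
       ped = pop@individuals[, c("id", "sire", "dam")],
       pheno = data.frame(id = rec$drp$id, drp = rec$drp$drp,
                          reliability = rec$drp$reliability),
       calving = rec$calving,
       tagIds = pop@markers$id[pop@tagMarkers],
       region = sprintf("23:%d-%d", pop@config@deletionStartBp,
                        pop@config@deletionEndBp))
})

## hand-built GenotypeData from a dosage matrix (markers x samples)
handGenotypes <- function(dosage, pos = NULL, hap1 = NULL, hap2 = NULL) {
  m <- nrow(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  markers <- data.frame(id = sprintf("m%03d", seq_len(m)), chrom = "23",
                        pos = pos, ref = "A", alt = "G",
                        stringsAsFactors = FALSE)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("s%03d", seq_len(ncol(dosage)))
  g <- GenotypeData(markers, dosage, hap1 = hap1, hap2 = hap2)
  colnames(g) <- colnames(dosage)
  g
}

## dosage matrix with given genotype counts at a single marker
countsRow <- function(n0, n1, n2) {
  matrix(rep(c(0L, 1L, 2L), times = c(n0, n1, n2)), nrow = 1)
}

trueCarrierStatus <- function(pop) {
  ind <- pop@individuals
  stats::setNames(ind$deletionCopies >= 1L, ind$id)
}
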