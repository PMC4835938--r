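---
title: "Mapping recessive lethal deletions from pedigreed livestock data"
author: "lethalscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive lethal deletions from pedigreed livestock data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lethalscan)
```

## The problem

A recessive lethal allele segregating in a livestock population produces no
affected live animals to examine: homozygous conceptuses die before or at
birth. What it does leave behind is a constellation of statistical traces,
and `lethalscan` implements the inference chain that assembles them into a
mapped candidate deletion:

1. a quantitative-trait signal — carrier sires transmit poorer calf
   survival, visible in an association scan of de-regressed proofs (DRPs);
2. a haplotype that is never observed homozygous although its frequency
   says it should be (the missing-homozygote test);
3. Hardy–Weinberg distortion inside the deletion, because a hemizygous
   genotype is miscalled as homozygous when only one allele is present;
4. loss of SNP-array signal intensity (Log2R ratio) and halved sequencing
   depth in carriers over the deleted segment;
5. an excess of stillbirths specifically in matings of a carrier sire to a
   daughter of a carrier maternal grandsire (MGS).

Every stage is exercised against a gene-drop simulator whose ground truth
is known, so the package doubles as a test bed for this class of designs.

## Models

### Weighted mixed models on de-regressed proofs

The whole-chromosome scan uses the half-sib *sire model*

$$y_{ij} = \mu + b\,x_{ij} + s_i + e_{ij}, \qquad
  s_i \sim N(0, \sigma_s^2), \quad
  \mathbf e \sim N(\mathbf 0, \mathbf W^{-1}\sigma_e^2),$$

where $y_{ij}$ is the DRP of bull $j$ in half-sib family $i$, $x_{ij}$ is
the allele dosage (0–2), and $\mathbf W$ is diagonal with DRP weights
$w = r^2/(1-r^2)$, the reliability capped at 0.98 so no weight exceeds 49.
Fine-mapping uses the *animal model*, replacing $s_i$ by a polygenic
effect $u \sim N(\mathbf 0, \mathbf A\sigma_u^2)$ with $\mathbf A$ the
additive relationship matrix from the pedigree (tabular method). The
*random haplotype model* (RHM) adds the two window haplotypes of each
animal as iid random effects sharing one variance $\sigma_h^2$, tested
with a likelihood-ratio test against the no-haplotype null on a
$\chi^2_1$ reference; the haplotype allele with the most negative BLUP is
designated the putative lethal-tagging haplotype, and re-entering its
per-animal count as a fixed cofactor should absorb the QTL signal.

The REML engine is written for exactly this family of models: the
restricted likelihood is profiled over $\sigma_e^2$ and maximized over log
variance ratios (hence the non-negativity constraint), with at most one
"dense" random term ($q \approx n$, e.g. the polygenic term) absorbed by a
one-off eigendecomposition and all remaining terms handled through the
Woodbury identity on a $q \times q$ system. Because the decomposition
depends only on the random structure and not on the fixed design, exact
per-marker re-estimation of variance components inside a scan is cheap; a
faster mode that profiles the components once under the no-marker null is
available and labelled in the result. Wald tests use the standard-normal
reference — with thousands of weighted observations the difference from
any plausible t reference is far below every tolerance used here.
Likelihood-ratio tests for a variance component use the plain
$\chi^2_1$ reference even though the null sits on the boundary of the
parameter space; this is conservative.

### Missing homozygotes

For a haplotype allele with frequency $q$ among $2N$ chromosomes of $N$
live genotyped animals, Hardy–Weinberg proportions predict
$\lambda = N q^2$ homozygotes. The probability of observing $k$ or fewer
under a Poisson model is `ppois(k, lambda)`; for $k = 0$ it is
$e^{-\lambda}$. Both the exact $\lambda$ and its rounded value are
reported — the rounded one reproduces a printed headline figure exactly,
the exact one is the default for new analyses. When many windows are
scanned, a Bonferroni-adjusted column over all tested alleles with
$q \ge 0.01$ is included.

### Deletion evidence channels

*Hardy–Weinberg scan.* Per marker, a 1-df $\chi^2$ compares observed
genotype counts with the expectation at the sample allele frequency,
without continuity correction; the direction (heterozygote deficit or
excess) is reported, and a conditional exact test is available for small
samples. A deletion produces a run of heterozygote-deficit markers, and
`inferDeletionRegion()` returns the span of the largest such run.

*Intensity rule.* An animal is called a deletion carrier when its mean
in-region Log2R ratio is below 0 **and** at least
$\lceil 0.97\,m \rceil$ of the $m$ region markers are called homozygous.
The ceiling form reproduces the usual operationalization of "97 % of
loci" (e.g. at least 135 of 139), leaving a 3 % allowance for genotyping
error.

*Read depth.* The ratio of mean windowed depth inside the candidate
region to outside is ~0.5 for single-copy carriers. The call cutoffs
(carrier < 0.7, noncarrier > 0.85, ambiguous between) are this package's
choice: at 8× genome depth aggregated over a 0.5-Mbp region the Poisson
ratio distributions of carriers and noncarriers are separated by far more
than the gap, so the misclassification probability is negligible.

### Mating-type analysis

Matings are classified by the carrier status of sire and MGS (the dam is
never genotyped; her carrier probability is inherited from her sire):
I = noncarrier × noncarrier-MGS daughter through IV = carrier ×
carrier-MGS daughter. Under Hardy–Weinberg proportions the expected
fraction of conceptuses homozygous for a causative allele at frequency
$p$ is $0,\; 0,\; p/(4(1+p)),\; (1+p)/(4(2+p))$ for types I–IV; the
type-IV fraction tends to $1/8 = 12.5\,\%$ as $p \to 0$. Calf survival is
analyzed with a linear mixed model on the 0/1 outcome — parity and
insemination month-year fixed, mating type fixed, MGS random with
covariance $\sigma_g^2 \mathbf A_s$ — matching routine practice for this
trait; a logistic variant is provided for sensitivity analysis only.
Within this module the outcome is coded 1 = stillborn; the recording
convention (1 = alive 24 h after birth) is converted explicitly at the
boundary by `buildMatingRecords()`.

## The synthetic-data generator

`simulatePopulation()` performs a Mendelian gene drop down a half-sib
pedigree: founders, then `nGenerations` rounds in which `nSiresPerGen`
males each sire `progenyPerSire` calves from dams sampled among earlier
generations' females. Defaults emulate a national dairy-cattle evaluation
at desk scale: a 20-Mbp chromosome with 400 evenly spaced SNPs, a 0.5-Mbp
deletion at 9.75–10.25 Mbp segregating at founder frequency 0.043, full
penetrance, 4 % baseline stillbirth, and DRPs on the additive-genetic-SD
scale with reliability-dependent noise.

Choices that matter, and why:

* **Tag window.** Ten SNPs (five on each flank of the deletion) are
  placed in complete founder linkage disequilibrium with it: deleted
  founder chromosomes carry the alt allele at all ten, intact ones the
  ref allele. LD then decays only by recombination. This makes every tag
  SNP an individually perfect tag, as sequence variants near a young
  deletion are; array panels, whose common SNPs tag such alleles only as
  a haplotype combination, are emulated at the window level.
* **Recombination.** Haldane map, uniform 1 cM/Mb. Crossover points
  falling inside the deleted segment are suppressed in gametes of
  carriers: the hemizygous region is unpaired at meiosis and cannot
  recombine. Without this, a no-interference model fabricates
  tag-without-deletion recombinants that pedigree amplification can turn
  into live "tag homozygotes" — an artifact, not biology.
* **Founders are live adults.** Founder genotypes are drawn from the
  post-selection distribution: a homozygous-deletion founder is
  rejection-resampled with probability equal to the penetrance. A
  breeding population under a recessive lethal contains no live
  homozygotes, and neither may its founders.
* **Genotype error model.** With probability `genotypeError` a homozygous
  call is perturbed to heterozygous and a heterozygous call to a random
  homozygote, so P(homozygous call | true homozygote) is exactly
  $1 - e$. The default $e = 0.002$ reflects typical SNP-array call
  discordance (0.1–0.2 %). Note the interplay with the intensity rule: at
  desk-scale panel density (10 in-region markers) the 97 % rule tolerates
  zero miscalls, so an unrealistically high error rate would reject true
  carriers purely as a panel-density artifact.
* **Hemizygote masking.** Inside the deletion a single-copy carrier is
  called homozygous for its one present allele; a live two-copy animal
  (possible only at penetrance < 1) is reported missing. Phased haplotype
  assays reflect the masking but not the sporadic dosage error; where an
  error makes dosage and phase inconsistent, the VCF writer encodes the
  dosage with arbitrary phase so dosages round-trip exactly.
* **DRP construction.** A bull's DRP is his polygenic breeding value
  (SD 1 by construction) minus $\delta$ if he carries the deletion, plus
  noise with variance $(1-r^2)/r^2$. The deletion term is
  $\delta = \tfrac12 P(\text{mate carrier}) \times \text{penetrance}$
  phenotypic SD, converted to the DRP scale by $1/\sqrt{h^2}$ with
  `drpH2 = 0.01`, the textbook direct-stillbirth heritability. At a
  carrier frequency around 10 % this lands the allele-substitution effect
  near $-0.6$ genetic SD, the magnitude at which such a QTL dominates a
  national scan.
* **Stillbirth outcome.** Homozygous-deletion conceptuses are recorded
  stillborn with probability `penetrance` (which deliberately absorbs
  late-gestation loss and farmer under-reporting — the observed type-IV
  excess in real data is below the theoretical 12.5 % for exactly those
  reasons); all other calves follow a liability-threshold model with
  heritability `drpH2`, giving the MGS random effect something real to
  absorb. Dead conceptuses enter the calving table but are never
  genotyped.

What the generator does **not** emulate: genotype imputation error,
maternal (indirect) genetic effects on calving, multi-chromosome genomes,
array-specific intensity artifacts (GC waves, batch effects), population
admixture, and selection on the trait besides the lethality itself.
Passing tests therefore show that the inference chain is correct *given*
clean phased genotypes and honest records, not that it is robust to every
failure mode of real data.

## QC placement

The marker filter applies, in order, a MAF floor (0.01), a Hardy–Weinberg
threshold ($p \ge 10^{-5}$) and an optional region exclusion, tallying
each removed marker once under the first criterion it fails. Placement
differs by stage, and deliberately so: association scans run on
MAF-filtered markers only, because a perfectly tagging SNP of a recessive
lethal violates Hardy–Weinberg proportions *by construction* — its
missing homozygotes are the signal — and at cohort sizes where
$Nq^2 \gtrsim 15$ an HWP pre-filter would delete the very markers that
carry the peak. The haplotype-window stage always excludes the putative
deleted region itself, whose miscalled genotypes would otherwise corrupt
phasing. Whether it should also apply the HWP threshold depends on the
tagging structure: on an array panel whose common SNPs tag the lethal
only as a combination, individual markers are HWP-clean and the filter
removes genuine artifacts; with sequence-perfect single-SNP tags (as in
this simulator) the same filter becomes a detector of the lethal and, at
large $N$, deletes the signal markers. The end-to-end pipeline applies
the threshold at its default cohort scale, where tags survive it; the
large-cohort analyses in the tests and README disable it for the window
stage and say so.

## Numerical choices

* REML: log-parameterized variance ratios; 1-D problems use golden-section
  search to tolerance $10^{-10}$ (variance components then match
  closed-form ANOVA estimators on balanced designs to $10^{-6}$),
  multi-term problems use Nelder–Mead with relative tolerance $10^{-12}$.
  Non-convergence is flagged on the result, not raised. A response that
  the fixed effects fit exactly short-circuits to zero variance
  components.
* A singular fixed design is an error naming the aliased columns; inside
  scans a collinear marker (e.g. one in perfect LD with the cofactor) is
  flagged `not_estimable` instead, and monomorphic markers are skipped.
  An all-constant cofactor is dropped with a message, which makes the
  cofactor scan degenerate gracefully to the plain animal model.
* $-\log_{10} p$ is computed in log space from the normal tail, so it
  remains finite and consistent with $p$ to $10^{-10}$ even for extreme
  peaks.
* Missing dosages are mean-imputed within a scanned marker; missing
  genotypes are excluded pairwise from MAF and Hardy–Weinberg counts.
* Ties when picking top scan markers are broken by genomic position.

## Problem sizes

The test suite's planted-truth conditions are sized so every recovery
property is identified with margin: the missing-homozygote cohort has
~19,000 live genotyped animals (the scale of a national 50k panel) at a
founder deletion frequency of 0.05; the scan cohort has 1,200 founders
and ~3,400 phenotyped bulls, at which the planted QTL's peak
($-\log_{10}p \approx 16$–33) clears the largest founder-lineage drift
artifact (~8–14) in every seed examined; the intensity/depth cohort uses
an HD-density panel (50 in-region markers) over ~250 animals with a
carrier frequency near 16 %, matching the geometry under which the 97 %
homozygosity rule was designed; and the mating analysis uses ~10,000
calving records, giving on the order of 100 type-IV matings. The
end-to-end pipeline examples run a reduced ~2,000-calf configuration.

## Known limitations

* The linear model on a 0/1 outcome is the field's convention for this
  analysis, not the statistically ideal choice; the logistic option is
  provided for sensitivity, without an MGS random effect.
* The animal-model stages build a dense relationship matrix; they are
  intended for cohorts up to a few thousand animals per fit, matching the
  bull panels such analyses actually use (larger cohorts are subsampled
  by the pipeline's `animalModelMaxN`).
* The missing-homozygote test treats the homozygote count as Poisson;
  family structure adds mild overdispersion, which is why the neutral
  control is asserted at 3 standard deviations rather than at a nominal
  quantile.
* Breakpoint refinement (split reads), imputation and phasing of real
  data are out of scope: phased input is assumed correct.
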