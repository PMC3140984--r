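---
title: "Dissecting capacitating epistasis in an advanced intercross line"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting capacitating epistasis in an advanced intercross line}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem this package addresses

Long-term divergent selection for 56-day body weight in chickens produced a
high-weight (HWS) and a low-weight (LWS) line whose difference (~1341 g
between founder means of 1522 g and 181 g) is far larger than the sum of the
individually detectable QTL effects. A radial network of interacting loci --
a central hub (*Growth9*) whose high-line genotype *releases* the effects of
several peripheral loci -- accounts for much of this discrepancy:
capacitating epistasis hides cryptic variation in a suppressed background
and exposes it in a released one. `ailnet` implements the full analysis
tool-chain for studying such networks in an advanced intercross line (AIL):
an eight-generation pedigree between the two lines, genotyped on nine
selected chromosomal segments, phenotyped for 56-day weight.

Because the original pedigree is not publicly deposited, the package also
contains a first-class synthetic generator that emulates the study design,
so every downstream stage is exercised and tested without any download.

## Data model

The central genotype summary is the **line-origin contrast**: a per-marker
value in [-1, 1] giving the expected excess of HWS over LWS alleles for an
individual (in real data a rescaled line-origin probability; the simulator
emits the true contrast, optionally blurred). Contrasts are discretized at
+-0.4 into HH / HL / LL calls. The thresholds are deliberately conservative:
the heterozygote interval is wider than +-1/3 (the even split) because false
homozygotes are the costly error for stratified analyses; exact boundary
values fall into HL (strict inequalities).

Phenotypes are residualized once, on the full pedigree, as deviations from
their sex-by-generation class mean. All scans, class means, and effect
estimates consume these residuals. Residualizing before (rather than within)
each stratified analysis keeps the permutation logic simple -- permuting
residuals preserves the (phenotype, sex, generation) pairing exactly -- and
is equivalent to in-model fixed effects under balanced codings. The
alternative (re-residualizing within each stratum) was considered and not
adopted; it changes estimates only through stratum-by-class imbalance.

## Scans and significance

The **two-locus epistatic model** regresses the residual weight on marginal
additive (HH = +1, HL = 0, LL = -1) and dominance (HL = 1) codings of two
loci plus the four product terms (aa, ad, da, dd). Two nested F tests are
reported: full vs marginal-only (the interaction-improvement statistic used
throughout) and full vs intercept-only. Rank-deficient designs (an
unobserved genotype class) are fitted by pivoted QR; aliased terms are
reported by name and carry zero coefficients. The exhaustive 2D scan fits
every between-segment marker pair and selects, per segment, the marker whose
best pairing has the largest interaction statistic; exact ties break to the
lowest marker index.

One-dimensional scans report the additive-term F per marker, optionally
averaged over bootstrap resamples (200 by default, resampled to the original
size). Study-wide thresholds come from a permutation test: genotypes are
permuted against (phenotype, sex, generation) tuples, the maximal statistic
of each permuted scan is recorded, and the threshold is the empirical 95th
percentile (type-7 quantile) of 1000 maxima. Permuted scans are plain (not
re-bootstrapped) scans; the source analysis is ambiguous on this point and
re-bootstrapping inside each permutation would only inflate cost without
changing the null maximum's location materially.

A caveat the simulations make visible: the permutation null destroys *all*
genotype-phenotype association, including the long-range correlations that
family structure induces between causal loci and physically unlinked
markers. When a strong architecture segregates in a deep pedigree, pairs of
non-causal markers can therefore exceed the threshold through shared-family
signal. This is a property of the design (and of the emulated study's
strategy), not of the implementation; the bootstrap averaging exists
precisely to judge robustness of such peaks.

## Stratified effects and their summaries

For a conditioning locus, the HH and LL homozygote strata are formed
(heterozygous and missing calls belong to neither; strata smaller than 30
individuals -- configurable -- are refused downstream). Within a stratum the
additive effect of a tested marker is the least-squares slope of the
residual weight on the additive coding, with its standard error. Strata are
compared by a one-sided Wald test on the difference of the two independent
slopes. The emulated study never names its test, and a z-test reproduces
some of its printed p-values (0.048 -> 0.053, 0.046, 0.143, 0.055) but not
others (0.016, 0.011); rather than reverse-engineer, the Wald test is the
default and a stratum-label permutation test ships alongside
(`compare_strata_effects_perm`).

Network summaries add the stratified effects over the supplied pairs, form
the HH/LL ratio (flagged undefined when the LL sum is zero) and express each
sum as a percentage of the founder-line difference (defaults 1522 g, 181 g)
and optionally in phenotypic SDs. The **k-level decomposition** attributes a
triplet's total effect at increasing interaction order: each locus carries
its own marginal effect at k = 1; half of each of its two pair spans,
averaged, at k = 2; and a third of the triplet span at k = 3. "Span" is the
difference between the highest and lowest corrected genotype-class means of
the pair or triplet. Attribution totals are exact sums; rounding happens
only at report time.

## Genotype-phenotype maps

The **model-free map** classifies hub-homozygous individuals by how many of
the radial loci they carry as HH homozygotes (heterozygotes count as
"not HH"), giving 10 classes for four radial loci, each with a corrected
mean, s.e.m. and count; classes under 3 individuals are reported missing,
never zero.

The **parametric map** uses the orthogonal "statistical model" of the NOIA
framework: per-locus additive and dominance predictors are rescaled by the
*observed* genotype frequencies so that effect estimates stay uncorrelated
even away from ideal F2 proportions (at exactly (1/4, 1/2, 1/4) the scaling
reduces to the classical (-1, 0, 1) and (-1/2, +1/2, -1/2) codings).
Marginal effects plus all pairwise interactions are fitted jointly --
third-order terms are deliberately excluded so that the comparison between
observed class means and the collapsed parametric map isolates higher-order
structure. The map transformation is linear; values -> effects uses weighted
least squares with product-frequency weights, making the effects -> map ->
effects round trip exact (tested to 1e-8).

## Plane variances and R_p

For a locus triplet, the 27 corrected genotype-class means are partitioned
into three 9-cell planes sharing one genotype at a conditioning locus. Flat,
parallel, or translated planes indicate no effect, a marginal-only effect,
or interactions not involving the conditioning locus; *shape* differences --
unequal within-plane variances -- indicate that the conditioning locus
modulates the others. **R_p** is the ratio of the largest to the smallest
defined plane variance.

Numerical choices, all configurable:

* plane variance is the unweighted sample variance (divisor n-1) of the
  populated cell means; a count-weighted option exists, since the source
  leaves the weighting unstated;
* a plane needs at least 5 of 9 populated cells, and a cell at least 3
  individuals, for its variance/mean to be defined;
* a zero minimum variance makes R_p unbounded; such results are flagged
  `undefined-infinite` rather than given a pseudo-number, because the
  ratio's scale is dominated by its denominator;
* significance is deliberately left to an *optional* permutation null
  (phenotypes permuted against genotype triplets, empirical exceedance per
  value) -- clearly an addition of this package, as the original treatment
  leaves scaling and testing of R_p open.

The exhaustive scan evaluates all C(k,3) triplets times 3 conditioning
choices (60 values for six candidate loci) and ranks them.

One subtlety surfaced by simulation: in the three-locus capacitating
architecture (hub effect plus radial effects and synergy released only on
the hub-HH plane) the radial loci *also* modulate plane shapes -- released
and suppressed planes differ when conditioning on a radial locus -- so the
hub's R_p is the largest in expectation but not the only elevated one. This
mirrors the reciprocal capacitation reported for the real network. The
acceptance suite therefore measures hub recovery on the architecture's own
triplet; adding unlinked null candidates to the scan lowers the top-rank
recovery rate because radial-conditioned and occasionally noise-driven
ratios can overtake a noisy hub ratio.

## The synthetic world (and what a green test does not establish)

The generator reproduces the stated design: 59 founders (10 HWS males x 22
LWS females, 8 LWS males x 19 HWS females), generations F1..F8 of sizes
100, 100, 300, 100, 100, 100, 100, 400; nine marker segments with the
published physical bounds, 1 cM/Mb by default (per-marker genetic positions
are not published; the map file can override); meiosis by the Haldane map
function within segments, independence across segments; random mating
within generation with balanced sexes (the real mating scheme beyond the
founder crosses is not described -- any scheme with the stated sizes is
admissible). Contrasts are exact line-origin dosages; an optional
truncated-Gaussian `blur` stresses the +-0.4 thresholds the way estimated
contrasts would.

Phenotypes are genotype value + sex effect (100 g, a plausible dimorphism;
the source gives none) + optional generation effects + Gaussian noise with
SD 127 g, the reported F8 phenotypic SD. Architecture presets are
calibrated so stratified effects land on the published scale: released
per-locus effects of ~40-50 g (Table-2-like HH strata), hub effect 25 g
(suppressed-background effects ~20 g), synergy 28 g giving a best-to-worst
triplet span of ~200 g against the printed 207 g.

Deliberately not modelled: founder haplotype diversity (lines are treated
as fixed for alternative alleles -- real founders retained residual
heterozygosity), X-linked inheritance, selection within the AIL, and the
IBD-matrix machinery that estimates contrasts from raw genotypes. A green
test therefore establishes that the *analysis machinery* behaves correctly
on a faithful rendering of the design, not that the original point
estimates are reproduced -- those require the real pedigree, and the
acceptance targets are restricted to the printed worked arithmetic plus
property-based criteria.

## Determinism and configuration

A single integer seed drives the pipeline; the generator consumes it in the
documented order pedigree -> meiosis -> noise. `analysis_config()` carries
every tunable with the study's values as defaults (thresholds +-0.4, B =
200, N = 1000, alpha = 0.05, line means 1522/181, minimum stratum 30 --
the real strata held 229-377 individuals, the source states no minimum).
Configs round-trip through YAML; the pipeline writes a manifest (package
version, R version, full config, seed) sufficient to reproduce every output
table byte for byte.

## Known limitations

* Family structure inflates the two-locus interaction statistic for
  non-causal pairs when a strong architecture segregates (see above); the
  permutation threshold controls the global null only.
* The 2D scan's selection criterion ("strongest support for interactions")
  is operationalized as the maximal full-vs-marginal F over pairings; the
  source does not name its exact criterion.
* R_p has no closed-form null; the provided permutation null conditions on
  the observed genotype frequencies and is exchangeable only under the
  global no-association hypothesis.
* Stratified scans reuse the residuals of the full pedigree; within-stratum
  re-centering would differ under strong class imbalance.
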