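---
title: "Benchmarking local ancestry inference and scanning for ancestry deviation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking local ancestry inference and scanning for ancestry deviation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laiscan)
```

## The problem

In two-way admixed cohorts -- the motivating case is Neolithic European
genomes, where migrating Anatolian farmers admixed with local
hunter-gatherers roughly 35 generations before the sampled individuals,
leaving ~20% hunter-gatherer ancestry -- local ancestry inference (LAI)
assigns each position of each haplotype to one of the two source
populations. Three downstream analyses hang off those assignments:
per-individual global ancestry proportions, ancestry tract lengths
(which date the admixture pulse), and genome-wide scans for loci whose
local ancestry deviates from the genome-wide average, the signature of
post-admixture selection.

Ancient-DNA conditions are hostile to LAI: source panels are tiny and
unbalanced (here 48 hunter-gatherer vs 7 farmer diploids), genotypes
are imputed with residual error, phasing carries switch errors, and
some cohorts are pseudohaploid. `laiscan` provides a simulator that
emulates exactly these conditions with known truth, two in-package LAI
engines, and the benchmarking and scan machinery, so that every claim
about the pipeline can be tested end to end without any external data.

## The synthetic cohort

`simulationConfig()` / `simulateCohort()` generate:

* **Source divergence.** Per site an ancestral frequency is drawn
  Uniform(0.05, 0.95) -- sites near fixation are excluded, mirroring a
  MAF-filtered panel -- and each source population's frequency follows
  the Balding–Nichols distribution
  Beta(f(1−F)/F, (1−f)(1−F)/F) with F the target divergence
  (default `Fst = 0.1`, a plausible hunter-gatherer/farmer value; the
  realized Hudson-estimator divergence is checked in the tests).
* **Truth tracts.** Ancestry along each admixed haplotype is a
  two-state Markov jump process in genetic distance whose switch rate
  out of an ancestry with proportion $p_a$ is $T(1-p_a)/100$ per cM
  (defaults $T = 35$, $p = 0.2$). This is the stationary approximation
  to a $T$-generation pedigree: interior tract lengths are exactly
  exponential with the single-pulse rate
  $\lambda = T(1-p_\mathrm{pop})/100$, so the simulator realizes the
  same tract-length theory the fitting code assumes, and the
  genome-wide expected hunter-gatherer fraction is $p$. It is a stated
  modeling assumption, not an inference about the true Neolithic
  process.
* **Selection.** `injectSelection()` shifts the local hunter-gatherer
  probability to $p + \delta$ at a locus, tapering linearly to $p$ at a
  radius (default experiments use $\delta = \pm 0.15$, radius 2 cM).
  Each affected haplotype is overridden on one contiguous interval, so
  the marginal deviation is exact at every site while tract structure
  stays blocky. This is locus-conditioned resampling, not forward
  simulation of fitness -- it gives exact control of the deviation the
  scan must recover.
* **Noise.** Per-allele genotype error (default 0.005, a plausible
  post-imputation residual), phase-switch points laid down as a Poisson
  process (default 0.01 per cM; the truth labels are swapped together
  with the alleles, so truth stays aligned with the emitted phasing),
  and optional pseudohaploid collapse (one random allele per individual
  per site).
* **Geometry.** Sites are evenly spaced at 1 cM = 1 Mb with a default
  density of 150 SNPs/cM (16,500 sites on a 110 cM chromosome),
  matching the density of a genotype-array-scale panel
  (~570k autosomal SNPs over ~3,500 cM).

What the generator does **not** emulate: real LD between nearby sites
within a source population (sites are drawn independently given the
frequencies), reference-panel phasing artifacts beyond simple switch
points, post-mortem damage profiles, temporal drift between sources
and admixed cohort, and more than two sources. Tests passing on this
generator therefore validate the pipeline's statistics under the
stated model, not LAI accuracy on real ancient genomes.

## The two engines

**Minimum-mismatch windows** (`callMismatch()`): for each haplotype and
sliding window (1 Mb span, 0.5 Mb step), the Hamming mismatch count
against every source haplotype is computed, and the window takes the
ancestry of the panel attaining the smaller minimum; exact ties break
to the farmer (majority) ancestry and are counted. Each SNP receives
the nearest window center's label. The pseudo-posterior
`bestOther / (best + bestOther)` is reported but is *not* calibrated --
filtering it at 0.9 removes most calls, which is why the study-style
posterior filter is only applied to the HMM.

**Two-state haplotype HMM** (`callHmm()`): per haplotype, hidden states
farmer/hunter-gatherer, switch probability
$1 - e^{-T(1-p_a)d/100}$ over a gap of $d$ cM (the same rate structure
as the tract model, so calling and tract theory are mutually
consistent), Bernoulli emissions at the source allele frequencies
(clamped to $[10^{-3}, 1-10^{-3}]$, error-adjusted), and posterior
decoding by scaled forward–backward (compiled; exactness is verified
against brute-force path enumeration on short chains). An effective
population size parameter is accepted for interface parity with
drift-aware callers but unused: the per-haplotype two-state model has
no drift term. Read-count emissions (binomial with error) support
pseudohaploid data; a single sampled allele is the one-read case.

**Frequency refinement.** With 14 farmer haplotypes, the panel estimate
of a site's farmer frequency has a sampling error of up to ~0.13 --
and that error is *shared by every admixed haplotype*, producing
method-systematic local miscalling that dominates the variance of
population-level ancestry tracks (about 3x the pure drift noise in the
default simulation). `callHmm(refineIterations = 1)` re-estimates the
source frequencies once from the posterior-weighted admixed alleles,
pooled with the panel counts as pseudo-counts; this is the in-package
analog of the joint source-frequency modeling that read-count HMM
callers perform. It raises per-site accuracy from ~0.94 to ~0.97 in
the default simulation and is the default in the scan harness
(`cohortMethodCalls()`), while `callHmm()` itself defaults to 0 passes
so that the plain engine's behavior (including its source-size bias)
remains observable.

## Post-processing

* `recodePaths()` collapses 6-valued path codes onto the two sources
  (codes 3 and 4 are hunter-gatherer; 1, 2, 5, 6 farmer).
* `applyPosteriorFilter()` keeps calls with posterior strictly > 0.9
  by default (the threshold is strict: a call at exactly 0.9 drops).
* `unkink()` is the rephasing step: where both haplotypes of a diploid
  switch ancestry simultaneously in opposite directions, the haplotype
  assignments are swapped from that point on. The total switch count
  never increases. At realistic SNP densities genuinely coincident
  opposite switches are vanishingly rare, so unkinking recovers the
  truth phasing almost always; on sparse grids it can merge real
  switches, which is a discretization effect.
* `dedupMaleX()` drops the duplicated haplotype of pseudo-diploid
  males after X-chromosome calling; `makePseudoDiploid()` builds the
  pseudo-diploid input for diploid-only callers.
* `correctChromosomeBias()` shifts each chromosome's per-SNP mean
  ancestry by (chromosome mean − genome mean), the standard remedy for
  callers that inflate whole chromosomes; it corrects the symptom
  without diagnosing its cause.

## Tract lengths and admixture dating

`extractTracts()` walks maximal same-label runs per haplotype, with cM
lengths between the first and last SNP of a run. Missing-call runs of
at most 2 SNPs (flag-controlled) are bridged when both flanks agree:
posterior filtering would otherwise shatter tracts. Whether missing
calls should break tracts is a genuinely open choice, so both
behaviors are available.
Tracts touching chromosome ends carry censored flags.

The single-pulse theory is
$P_\mathrm{bin} = e^{-\lambda b_\mathrm{start}} - e^{-\lambda b_\mathrm{end}}$
with $\lambda = T(1-p_\mathrm{pop})/100$ per cM; `binProbability()` and
`expectedCounts()` evaluate it ($\lambda(T{=}35, p{=}0.2) = 0.28$,
mean hunter-gatherer tract 3.57 cM). `fitSinglePulse()` estimates $T$
by maximum likelihood: tracts at or above the 10 cM exclusion
threshold contribute an exponential density term if uncensored and a
survival term if censored, both conditioned on exceeding the
threshold. The memorylessness of the exponential keeps this
closed-form testable (the MLE equals
$100\,n_\mathrm{unc} / ((1-p)\sum(\ell - \ell_\mathrm{min}))$), while
the code path uses 1-D likelihood optimization on $T \in [1, 500]$
with a 95% profile-likelihood CI, and warns when the estimate pins at
a boundary (the all-censored, full-chromosome pathology). The
chromosome-length upper-truncation correction of the full TRACTS-style
model is intentionally out of scope.

## The deviation scan

Per method: the per-SNP population mean hunter-gatherer ancestry
(`snpMeanAncestry()`, SNPs under 50% call rate dropped), then
51-SNP sliding windows with step 1 (`windowZ()`). The window statistic
is the mean of per-SNP means;
$Z = (\mathrm{stat} - \bar{m}) / \mathrm{SD}(\mathrm{stat})$ where
$\bar{m}$ is the genome-wide mean of per-SNP means and the SD is taken
over all unmasked windows. Two standardization conventions are
defensible (the SD of the window statistic, or the per-SNP SD); the
window-statistic SD is the default because it makes the track
self-standardized -- null SD = 1, so |Z| maps directly onto normal
p-values -- and the per-SNP variant is one flag away. Windows overlapping masks (long-range LD intervals, 2.5 Mb
flanks of unmappable regions via `unmappableFlanks()`), truncated by
chromosome ends, or mostly uninformative are masked.

Methods are integrated by
$Z_\mathrm{combined} = \sum_i Z_i / \sqrt{\mathbf{1}^\top \Sigma \mathbf{1}}$
with $\Sigma$ the covariance of the method Z tracks estimated
genome-wide on jointly unmasked windows (`combineZ()`). Because the
denominator is exactly the sample variance of the sum, the combined
track has unit SD by construction -- the null-calibration tests verify
mean within ±0.1 and SD within [0.85, 1.15] without any tuning knob.
With $\Sigma = I$ this is Stouffer's method; identical unit-scale
tracks pass through unchanged. Covariance (not correlation) is used as
written, with the correlation variant behind a flag.

Discovery: windows with $|Z| > 3$ merge into regions when lead SNPs
are within 1 Mb (well below the 2 Mb replication radius, so merging
cannot create replication ambiguity); the region lead is the max-|Z|
window, and positive Z means excess hunter-gatherer ancestry. Under
honest unit-SD calibration a ~330 cM genome contains roughly one null
$|Z|>3$ excursion per scan (windows are autocorrelated on the ~3.5 cM
tract scale, giving on the order of 100 effective tests), so discovery
alone is *expected* to over-call -- which is precisely why the
workflow replicates: `replicateRegions()` demands a matching-sign
window with $|Z| \ge 2.84$ within 2 Mb of the lead in an independent
cohort analyzed with a single method. The default replication
threshold 2.84 is a conventional Bonferroni-style constant for ten
discovery hits, kept as a fixed default even though no standard-normal
quantile of 0.05/10 reproduces it exactly (two-sided gives 2.81,
one-sided 2.58); `pToZThreshold()` is the formulaic route. Two-sided
p-values are the default for discovery; X-chromosome-style thresholds
(0.05/2 at one side, giving 1.96) use the one-sided mode.

`lowAncestryDiagnostic()` implements the misclassification check:
individuals with reference global ancestry below 0.1 are close to the
pulse and should show *smaller* deviations at truly selected loci; a
region whose subset deviation is at least half the full-cohort
deviation is flagged `misclassification-suspect`. The 0.5 ratio makes
a qualitative argument operational and is exposed as an argument.

## Numerical and design choices

* Labels are coded 0 = farmer, 1 = hunter-gatherer, −1 = missing; all
  proportions in the package are hunter-gatherer fractions.
* MAF, INFO-score and posterior thresholds are strict `>` as printed.
* Site coordinates are 1-based inclusive bp; BED masks are converted
  from 0-based half-open on load; bins and windows are anchored at
  position 1 of each chromosome for determinism.
* Genetic positions absent from a map are linearly interpolated,
  and extrapolated at the chromosome's mean cM/bp rate beyond it.
* HMM source frequencies at 0 or 1 are clamped to $[10^{-3}, 1-10^{-3}]$
  (logged); 0.5-posterior ties and mismatch ties break to the farmer
  (majority) ancestry, deterministically.
* Zero-variance bins/individuals yield missing values, never NaN
  propagation; constant ancestry tracks mask the whole scan with a
  warning rather than dividing by zero.
* Degenerate inputs: empty site filters are allowed (logged); a
  chromosome shorter than one window is masked with a warning; fitting
  with no tracts above the length threshold is an error that reports
  the exclusion count.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run entirely on simulated
data at sizes a laptop handles comfortably: tract-dating recovery uses
200 haplotypes x 35 chromosomes x 150 cM (about 3,600 tracts above the
10 cM cut per replicate, giving T̂ standard error well under one
generation); the scan experiments use 150 diploids over ~50,000 SNPs
on three 110 cM chromosomes with deviations of ±0.15 injected at two
loci, and an independent equally-sized cohort for replication; null
calibration uses 100 diploids over 20,000 SNPs. These sizes keep every
Monte-Carlo bound (e.g. "≥ 90% of seeds") at adequate resolution while
the full suite stays in the tens of minutes.

## Known limitations

* The simulator's Markov tract process ignores pedigree-induced
  deviations from exponential tract lengths and interference; it is
  the same single-pulse model the estimator assumes, so
  parameter-recovery tests validate the estimator, not the model.
* The mismatch engine is a from-scratch window classifier in the
  spirit of lowest-number-of-mismatches callers; its internals are not
  a reimplementation of any specific tool.
* `Ne` is accepted but unused (documented above); read-count emission
  handles pseudohaploid single reads and binomial read counts, not
  full damage-aware genotype likelihoods.
* External callers (random-forest, copying-HMM, neural-path methods)
  are supported only through their msp-format outputs via
  `readMspCalls()`; the package never recomputes them.
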