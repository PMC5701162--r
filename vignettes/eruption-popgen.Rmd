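---
title: "Methods: heterochronous population-genomic comparison across an abrupt decline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterochronous population-genomic comparison across an abrupt decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eruptpop)
```

## The problem

Detecting the genetic footprint of a recent, modest population decline is
hard: one or two generations of drift change allele frequencies only
slightly, and small marker panels (microsatellites, mtDNA) are easily
dominated by sampling noise. The design this package supports is
*heterochronous*: the same populations are genotyped at hundreds of
genome-wide SNPs shortly before and shortly after a discrete event (here, a
volcanic eruption that reduced two rodent populations by roughly 25–40%),
and diversity, differentiation and demographic-signal statistics are
compared across the two time points under resampling designs that equalize
sample sizes.

The package is organized as an analysis workflow (`analysis/01_simulate.R`
… `analysis/06_demography.R`) over a library of tested statistical
functions; `run_compare()` composes the whole comparison into a single
deterministic report.

## Data model

Genotypes are biallelic SNPs in diploid individuals, encoded as
alternate-allele dosages 0/1/2 with `NA` for missing calls
(`geno_matrix()`), read from and written to VCF v4.2. Sites live on
"target regions" (capture targets of ~1,200 bp); positions are 1-based,
and every windowed statistic uses half-open intervals `[start, start +
width)` on those positions. Genotypes are treated as unphased throughout;
phase separators in VCF input are accepted and ignored. Missing-data
policy belongs to the statistics, not the I/O: every per-site frequency is
complete-case for that site.

Per-sample metadata (population, period pre/post, sex, age class, burrow
system) drive the grouping and the resampling designs. Burrow systems
matter because one study species is colonial: same-burrow animals may be
close kin, which the one-per-burrow designs control for.

## The synthetic-data generator

No empirical genotype dataset ships with the package, so `simgen`
provides a forward Wright–Fisher simulator whose presets emulate the
two-species eruption sampling design, and which doubles as the
ground-truth test bed for every downstream statistic.

* **Forward, not coalescent.** The event of interest is 1–2 generations
  deep; forward simulation makes the instantaneous decline and the
  post-event generations explicit. Per generation and deme, allele counts
  are binomially resampled (`2N` trials); symmetric migration mixes deme
  frequencies before the draw. No mutation, selection, linkage or
  overlapping generations — over a 10-generation window these contribute
  negligibly compared to drift.
* **Founding frequencies** are drawn from a neutral-spectrum-shaped
  density (∝ 1/x truncated to `[1/(2Ne), 0.5]`), so simulated panels have
  realistic minor-allele-frequency spectra; a uniform option exists for
  calibration tests where equal mass across frequencies is convenient.
* **Kin structure**: within a multiply-sampled burrow, the whole burrow is
  a full-sib family with probability `sibship_rate`; sibs receive one
  allele from each of two parental genotypes drawn from the deme
  frequency. Deeper pedigrees are out of scope.
* **Presets.** `speciesA` (colonial): two demes, 17 pre-event samples over
  13 burrows, 31 post-event over 9 burrows, 9 from the second deme sampled
  only post-event, 531 SNPs, 40% decline, `sibship_rate = 0.3`, weak
  migration (0.005). `speciesB` (solitary): one deme, 12 pre / 17 post,
  449 SNPs, 25% decline, no kin structure. The pre-event effective sizes
  are unknown for such field populations; the presets use Ne = 300
  (colonial, geographically restricted) and Ne = 500 (widespread
  solitary) as plausible field-scale values, with 8 pre-event and 2
  post-event generations (sampling spanned roughly two years ≈ two
  generations after the eruption). Loci that are
  monomorphic in the drawn sample are re-simulated until the preset's
  exact segregating-panel size is reached, mirroring the fact that
  empirical SNP panels are ascertained to be variable.

Everything stochastic flows from one integer seed, and identical
(preset, seed) pairs produce byte-identical VCF and metadata files.

What the simulator does *not* emulate — and hence what green tests do not
certify about real data: genotyping error and allele dropout, depth- and
quality-dependent missingness (simulated data are fully called), linkage
within target regions, ascertainment toward the discovery sample, and
selection. Statistics here are genotype-based; low-coverage capture
studies often work from genotype likelihoods instead, which behaves
differently at low depth.

## Site filters

Before comparison, the panel is reduced to sites plausibly evolving
neutrally:

* **Hardy–Weinberg**: the exact conditional (Levene/Haldane) test,
  two-sided by probability mass. An exact test rather than chi-square
  because per-population sample sizes are 9–31. It is computed **per
  population**, and a site is removed if it fails in any of them — pooling
  populations would let Wahlund structure mask genotyping artefacts. The
  default alpha of 0.05 is uncorrected (consistent with the handful of
  removals reported in comparable studies); a Bonferroni option exists.
  Being discrete, the exact test's null p-values are conservative, never
  uniform; the tests assert the rejection-rate bound rather than
  uniformity.
* **FST outliers**: an FDIST-style scan. Per site, expected
  heterozygosity He and Weir–Cockerham FST are computed; a neutral
  envelope of `n_sims` sites is then simulated at the observed multi-locus
  FST using the island-model stationary approximation (deme frequencies
  Beta-distributed around an ancestral frequency resampled from the data,
  variance `F p (1-p)`), with genotypes drawn at the observed sample
  sizes. Each observed site gets an empirical upper-tail p-value against
  the quarter of simulated sites nearest to it in He — a sliding window
  rather than fixed He bins, because the empirical p floor `1/(k+1)` must
  be finer than the Benjamini–Hochberg rank-1 threshold `fdr/m` for a
  lone outlier among `m ≈ 500` sites to be detectable at the default
  50,000 simulations. Only the upper (directional-selection) tail is
  tested, matching the filter's purpose; balancing selection is not
  sought. This is a desk-scale approximation of the coalescent FDIST
  machinery, not a re-implementation of it.

Filtering is idempotent, and the report reconciles exactly:
kept + removed = input.

## Diversity statistics

* **Mean heterozygosity** has an explicit denominator mode, because the
  scale differs by orders of magnitude: `"snp_sites"` (per non-missing SNP
  call, the natural scale for a SNP panel) and `"all_callable_sites"`
  (per bp of callable sequence, the scale on which capture studies
  usually publish, ~10^-3). Published per-bp values cannot be reproduced
  from a SNP panel without the callable length, which is why both modes
  exist and are reported side by side.
* **Per-site θW and π** use the standard unbiased forms with per-site
  complete-case allele counts: `π = c(n−c)/C(n,2)`,
  `θW = [segregating]/a_{n−1}`.
* **Tajima's D** per 100-bp window, from the windowed segregating-site
  count and summed per-site pairwise differences, with the 1989
  normalizing constants evaluated at the minimum non-missing allele count
  across the window's sites (a conservative choice under missingness;
  windows need ≥ 4 haplotypes and ≥ 1 segregating site). The window step
  defaults to the width (tiling); a step argument gives overlapping
  windows, for designs where overlapping "sliding" windows are wanted.
* **Folded SFS** under equalized subsampling: `subsample_n` individuals
  drawn without replacement, minor-allele counts tabulated, averaged over
  20 iterations. Even-`n` ties (`c = n/2`) fold into the `n/2` class
  once.
* **Inbreeding F** is the method-of-moments excess-homozygosity
  coefficient with the small-sample `2n/(2n−1)` correction, computed
  against panel-wide allele frequencies.
* **Private and shared alleles** count ref and alt alleles separately by
  presence/absence across populations under 100× equalized subsampling.
  The spread of a resampled count is reported as the SD across iterations
  (presented as the "±SE" of the design, since the iterations are the
  sampling distribution being summarized).

## Differentiation

* **FST**: Weir & Cockerham (1984) variance components, multi-locus
  ratio-of-sums. Chosen because it admits the small negative estimates
  that unstructured data produce;
  sites need ≥ 2 genotyped individuals per population.
* **PCA**: Patterson normalization (center `2p`, scale `sqrt(2p(1−p))`),
  mean-imputed missing dosages, eigendecomposition of the
  individual-covariance; axis signs fixed by making the
  largest-magnitude loading positive. No LD pruning — capture panels here
  average ~1 SNP per region.
* **Admixture**: the binomial mixture model
  `g_ij ~ Bin(2, Σ_k q_ik p_jk)` fitted by plain EM block updates from 10
  random starts (best kept). Vanilla EM is transparent and adequate at
  ~500 sites × ≤ 60 individuals; it is also slow near weak optima, so
  fits on essentially unstructured data may return `converged = FALSE` at
  the iteration cap with the trace still creeping — the trace is
  returned so this is visible. The likelihood is monotone by
  construction; frequencies are clamped to `[1e-9, 1 − 1e-9]`.

## Resampling designs

Four schemes (`individuals`, `loci`, `one_per_group`, `sex_partition`)
share one engine; iterations are seeded `seed + iteration` so any single
iteration is reproducible alone. Locus subsampling is without replacement
up to the panel size and with replacement (with a warning) beyond it —
the study's 10,000-locus subsamples from a ~500-SNP panel are only
possible with replacement. Note the statistical consequence: without
replacement, the finite-population correction makes the SD fall *faster*
than `1/sqrt(n)` as `n` approaches the panel, so the `1/sqrt(n)` scaling
law is only clean when `n` is well below the panel size; the scaling
tests therefore use a ~4,000-SNP simulated panel with subsamples ≤ 800.

The KS test enters through pre/post comparisons of per-site
heterozygosity distributions (the unit is per-site values; configurable,
a design decision, so it is configurable) and through the mismatch
comparison below. Exact small-sample p-values come from R's `psmirnov`
machinery; Welch's t uses Satterthwaite df, with the degenerate
both-samples-constant case defined as `t = 0, p = 1` when means agree.

## Demographic signals

* **Mismatch distributions** use the L1 distance between dosage vectors
  over mutually non-missing sites — the count of allele differences
  between two unphased diploid genotypes. An identity-by-state
  alternative (`ibs_mismatch`) counts differing genotypes instead; the
  metric is always recorded in the object.
* **Raggedness**: published conventions differ, so the package pins one
  and tests it: classes run contiguously from 0 to one past the largest
  observed difference (absent classes padded with 0), and
  `r = Σ (x_i − x_{i−1})²` over that axis — a trailing fall term, no
  leading boundary term. A uniform five-class distribution gives
  `r = 0.04`; a single interior spike gives `r = 2`. The index is
  scale-free. Values are comparable within this package, not asserted
  identical to any external implementation.
* **The centered/re-scaled comparison** standardizes each population's
  per-pair difference values (not the binned frequencies) to mean 0, SD
  1, removing location and scale so the KS test compares shape only.
* **The survivorship simulation** asks what the decline alone — with no
  subsequent drift — should do: designate 50% of the pre-event sample as
  survivors at random, 100 times. Random subsampling preserves expected
  heterozygosity exactly, so this design's correct outcome is a null
  result; the contrast (heterozygosity *does* decay once generations at
  the reduced size elapse, at rate `(1 − 1/(2N))^t`) is exercised in the
  tests against the closed form.

## Numerical and design choices

* One root seed per run; every stage derives fixed offsets from it, and
  reports are byte-identical across reruns of the same configuration.
* Multi-locus FST and mean-FST envelopes use ratio-of-sums (not mean of
  ratios), the standard variance-stable choice.
* The EM convergence criterion is a log-likelihood gain below `tol`
  (default 1e-6); non-convergence is reported, never an error.
* Degenerate inputs are contracts, not surprises: monomorphic sites give
  HWE p = 1; sites with < 2 alleles are excluded from diversity with a
  message; windows without segregating sites are omitted; an individual
  with `L = E_hom` has undefined F, returned as `NA` with a message.
* Statistics undefined on a resampling draw trigger a bounded redraw (10
  attempts) and then an `NA` with a warning.
* Report-wide p-values are also Benjamini–Hochberg adjusted, since one
  run produces several tests.

## Problem sizes

The test suite and the acceptance script are sized to run on a laptop
core in minutes: estimator calibration uses 2,000 neutral sites;
replicate-based checks use 20–50 replicates of 150–530 loci; the outlier
power check uses the full 50,000-simulation envelope; end-to-end runs use
the two presets at their natural sizes (531/449 SNPs, 57/29 samples).
These sizes are the package's own choices for routine verification; all
scale linearly if enlarged.

## Known limitations

Genotype-likelihood-based estimation (low-coverage designs), multiallelic
sites, phased haplotype statistics, mismatch-model fitting (τ, θ
parameters), Bayesian migration-model comparison, and LD-aware methods
are out of scope. The outlier scan approximates the island-model
conditional FST distribution with a beta envelope; for very small sample
sizes or extreme He this envelope is coarser than a full coalescent
simulation. The admixture fitter is unaccelerated EM; for thousands of
individuals a quasi-Newton implementation would be preferable.
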