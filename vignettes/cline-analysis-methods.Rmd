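---
title: "Methods: geographic cline analysis across a contact zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geographic cline analysis across a contact zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinescan)
```

## The problem

Post-glacial recolonisation from separate refugia leaves secondary contact
zones: transects along which two lineages meet and admix. Loci involved in
maintaining such a zone — whether by environmental selection or intrinsic
incompatibilities — show *clines*: sharp sigmoid transitions in allele
frequency around the zone, against a background of loci whose frequencies
are flat, drift gently with distance, or change linearly. `clinescan`
identifies clinal alleles along a one-dimensional transect, estimates the
strength of selection maintaining them, and checks whether candidate SNPs
from external genome scans are enriched for clines. Its synthetic generator
emulates a Fennoscandian forest-tree resequencing design (roughly 12
populations along ~1,400 km running south from 69.06° N, 22.55° E, 10–35
diploids each) so that every stage is testable without any external data.

## Cline models

The transect coordinate $x$ is the great-circle distance (km) from the
northern reference point. The sigmoid core is

$$P(x) = p_{min} + (p_{max} - p_{min})\, g(x), \qquad
  g(x) = \frac{1}{1 + e^{-4(x - c)/w}},$$

so that $c$ is the position of steepest change and the width $w$ is the
inverse of the maximum slope: $P'(c) = (p_{max}-p_{min})/w$. Four model
variants differ in which parameters are free:

| model | free parameters | k |
|-------|-----------------|---|
| I     | $c, w$ (ends fixed)                         | 2 |
| II    | $c, w, p_{min}, p_{max}$                    | 4 |
| III   | I + tails $\delta_L, \tau_L, \delta_R, \tau_R$ | 6 |
| IV    | II + tails                                  | 8 |
| null  | uniform $p_0$                               | 1 |

Stepped models III/IV replace the core beyond the junctions $c-\delta_L$
and $c+\delta_R$ with exponential tails whose log-slope is a fraction
$\tau \in [0,1]$ of the junction slope; both tails are continuous with the
core at the junction (enforced to $<10^{-9}$ in tests). Under migration–
selection balance $w \propto \sigma/\sqrt{s}$, which is what later turns a
fitted width into a selection coefficient.

Whether model I's fixed ends should be 0/1 or the observed end frequencies
is genuinely open; we default to the observed frequencies of the two
transect-end populations (`end_fix = "observed"`) with 0/1 available as
`end_fix = "unit"`. In recovery simulations at 15 diploids per population
the observed-ends variant is unbiased but disperses the width estimate
(median relative error ≈ 0.32), because end-population sampling noise
propagates into $w$; the free-ends model II is the calibrated estimator
(≈ 0.22) and is what we use for parameter-recovery studies.

## Likelihood and fitting

Allele counts are modelled binomially: with $k_i$ focal-allele copies of
$n_i$ sampled at position $x_i$,

$$\ell = \sum_i \log\binom{n_i}{k_i} + k_i \log P(x_i)
  + (n_i - k_i)\log(1 - P(x_i)),$$

with predictions clamped to $[10^{-6}, 1-10^{-6}]$ so boundary parameters
stay finite. Environmental variables (normalised to $[0,1]$) use a
Gaussian likelihood with the noise scale profiled out by its MLE and
floored at $10^{-4}$; the profiled scale adds one free parameter to every
model.

Fitting is bounded multistart maximum likelihood, not MCMC: deterministic,
fast, and directly testable against a grid-search oracle. Bounds are
$c \in [\min x - L/2, \max x + L/2]$, $w \in [1, 10L]$ km ($L$ = transect
length), $\delta \in [0, L]$, $\tau, p_{min}, p_{max} \in [0,1]$. Twenty
starting points come from a Halton sequence over the box — width on a log
scale, since plausible widths span orders of magnitude — plus one
moment-based start (centre at the steepest observed frequency step). All
starts are scored, the best six are polished with L-BFGS-B (objective
tolerance ~1e-8, central-difference gradients computed in C++), and the
best polished optimum wins. An acceptance test verifies the optimizer
never falls more than 1e-3 log-units below a 101×101 grid-search oracle.

Each locus is re-polarised before fitting so the southern-half mean
frequency is at least the northern-half mean; the flip is recorded
(`polarity`) and the reported `p_north`/`p_south` columns undo it.

Parameter uncertainty, when needed, comes from a seeded parametric
bootstrap (`bootstrap_cline()`, default 200 replicates): data are redrawn
from the fitted cline and refit, giving percentile intervals for the free
parameters.

## Model choice, evidence ratios, clinal classification

Models are compared by AICc with $n$ = number of populations (the response
units are population frequencies; using total allele copies instead is a
documented alternative): $\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$.
The best model is the converged cline fit with lowest AICc, ties going to
the fewer-parameter model. The evidence ratio against the uniform null is
the ratio of the two models' Akaike weights,
$\mathrm{ER} = \exp((\mathrm{AICc_{null}} - \mathrm{AICc_{best}})/2)$ —
the pairwise form, which equals the two-model weight ratio regardless of
how many models enter the weight normalisation.

Rather than an arbitrary ER cutoff, a locus is *clinal* when its evidence
ratio strictly exceeds the empirical 99th percentile (linear interpolation)
of the distribution over all converged fits. Non-converged loci are never
clinal. At small sample sizes — fewer than 100 converged fits — the
threshold is flagged unreliable.

### Excluding linear gradients

A frequency gradient that is merely linear carries no transition zone and
must not be called a cline. The usual account is that such loci fail to
converge or drive the width to infinity. Under exact bounded MLE that is
not what happens: we measured that a strictly linear full-range ramp is
fit *well* by a moderate-width sigmoid (ŵ ≈ 0.7 L, converged, enormous
evidence ratio versus the uniform null). The exclusion is therefore made
explicit: a clipped linear model $P(x) = \mathrm{clip}(a + bx)$ (two free
parameters, like model I) joins every comparison, and a locus is excluded
as a linear gradient when the linear model (i) matches or beats the best
cline model on AICc *and* (ii) beats the null. Condition (ii) matters:
without it, flat loci — whose best linear fit has slope ≈ 0 and ties the
cline models — would be excluded too, distorting the evidence-ratio
distribution that the 99th-percentile threshold is computed over. Excluded
loci get evidence ratio 0 and can never be clinal.

## F_ST, isolation by distance, neighbourhood size

Pairwise differentiation uses Weir–Cockerham variance components computed
on allele counts — the haploid-sampling form of the ANOVA, since
`AlleleCountMatrix` does not retain genotype-level heterozygosity. The
among-individual component $b$ is therefore 0 by construction and
$\theta = a/(a+c)$; the deviation from the genotype-aware estimator is not
an acceptance surface and single-locus values are verified against an
independent `aov`-based oracle. Negative estimates are retained, never
truncated; multilocus values combine loci as a ratio of summed components
(ratio of averages), so monomorphic loci change nothing.

Isolation by distance regresses $F_{ST}/(1-F_{ST})$ on $\ln(\text{km})$
(Rousset's one-dimensional expectation); distance is haversine on a sphere
of radius 6371.0088 km. The neighbourhood size is defined as exactly
$N_S = 1/\text{slope}$ — the Rousset constant is deliberately not
disentangled because $N_S$ is only used downstream through
$s = N_S/w^2$. When the slope is not positive, $N_S$ is undefined and all
downstream selection coefficients are reported missing with an explanatory
status rather than failing. The Mantel test uses Pearson correlation of
off-diagonal entries with simultaneous row/column permutations (default
9,999, seeded); the p-value is two-sided on $|\rho|$ since sidedness is
not prescribed, $p = (1 + \#\{|\rho^*| \ge |\rho|\})/(1 + n_{perm})$.
Type-I error calibration is checked over 1,000 null simulations.

## Enrichment of selection candidates

Candidate-SNP sets (external genome scans, GEA) are tested for enrichment
of clinal alleles with an upper-tail hypergeometric test against a
background matched on the fitted end-frequency difference
$\Delta p = |p_{max} - p_{min}|$: for each candidate, all fitted loci in
the same $\Delta p$ bin (default width 0.05; neither the metric nor the
bin is prescribed, both are exposed) enter the background, as a union
without double counting. P-values are Bonferroni-adjusted across the sets
tested in one call. The p-value equals exact tail enumeration to 1e-12
for all background sizes up to 60 (tested exhaustively).

## Selection coefficients

For clinal candidate loci, $s = N_S/w^2$, using the IBD neighbourhood
size as a proxy for the dispersal variance. With widths of hundreds of km
and $N_S$ of a few hundred this lands in the weak-selection regime
($10^{-5}$–$10^{-2}$); because model I and model II produce systematically
different width scales, comparisons should stay within one best-model
class — the output keeps `best_model` alongside `s` for this reason.

## The synthetic transect

`sim_config()` defaults *are* the emulated study design: 12 populations
evenly spaced (±10 km seeded jitter) along the southward meridian from
69.06° N 22.55° E over 1,400 km; 15 diploids per population; 2,000
biallelic SNPs of which 1% are clinal (centre ~ U(500, 800) km to mirror a
contact zone centred near 650 km, width ~ U(150, 450) km — under a third
of the transect — and end frequencies giving $\Delta p \ge 0.7$); 40
linear-gradient loci; 500 neutral loci with isolation-by-distance
structure; the rest flat with uniform frequencies. Genotypes are drawn in
Hardy–Weinberg proportions within populations (inbreeding is not
modelled) and written as a VCF, so reading the VCF back reproduces the
generator's counts exactly. The 2,000-SNP default is a desk-scale stand-in
for the tens of thousands in a real resequencing panel; every rate in the
pipeline is locus-wise, so nothing but runtime changes with the panel
size.

Neutral loci are a logit-scale Gaussian process over populations with
covariance $\sigma^2 e^{-d/\rho}$ ($\rho$ = 300 km), scaled so a pair's
expected Weir–Cockerham $\theta$ matches the target mean pairwise
$F_{ST}$ (default 0.01) through the linearisation
$\theta \approx p_0(1-p_0)\,\sigma^2(1-e^{-d/\rho})$. This is a pragmatic
stand-in for stepping-stone coalescent structure: its $F_{ST}$-distance
curve is calibrated empirically in tests (realised mean ≈ 0.010 at 500
loci), and it yields a positive IBD slope, but it does not model linkage,
recombination or inversions — so passing tests say nothing about LD
structure in real data. The environmental table has 19 bioclim-style
variables: 12 clinal (co-centred with the allele clines), 5 linear, 2
flat, each with Gaussian noise (sd 0.02 on the normalised scale) and
arbitrary per-variable offset/scale so normalisation is exercised.

## Numerical choices and degenerate inputs

* Clamp $\varepsilon = 10^{-6}$; Gaussian sigma floor $10^{-4}$;
  optimizer tolerance ~1e-8; 20 starts, 6 polished.
* A fit whose best width sits on the $10L$ bound, or whose optimizer
  fails, is retained but flagged non-converged.
* Loci with any unsampled population are excluded before fitting (the
  likelihood is undefined there); loci with more than 50% of possible
  allele copies missing are dropped.
* Missing genotypes shrink $n_i$; nothing is imputed. How missing
  genotypes entered per-population frequencies in comparable analyses is
  unstated; shrinking $n_i$ is this package's convention.
* AICc requires $n > k + 1$ populations; models violating this are
  skipped with a reason, never fitted.
* Monomorphic loci: $\theta$ undefined, recorded missing, harmless in
  multilocus sums.
* Exact AICc ties resolve to the model with fewer parameters.

## Problem sizes used in the test-suite simulations

Simulation-based checks run at the design scale of the emulated study:
parameter recovery and model-selection sanity at 100 loci; specificity of
the 99th-percentile rule over 100 replicates of 200 loci (5% truly
clinal); Mantel calibration over 1,000 null simulations of 10 populations
with 999 permutations; neighbourhood-size recovery over 100 seeds; the
end-to-end recovery check on one full 2,000-SNP default simulation.

## Known limitations

* The F_ST estimator is allele-count (haploid-form) Weir–Cockerham; exact
  equality with genotype-aware implementations is not expected.
* Parameter uncertainty is not propagated into the classification (the
  bootstrap is a per-locus post-step); the evidence-ratio percentile is
  an outlier rule, not a test with controlled error rates.
* One-dimensional transects only; no two-dimensional cline surfaces, no
  concordance/coincidence tests across loci, no Bayesian fitting.
* The generator's neutral process is not a coalescent; its IBD slope is
  an emergent, calibrated property, not Rousset's exact expectation.
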