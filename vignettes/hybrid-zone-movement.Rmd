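---
title: "Inferring hybrid-zone movement: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring hybrid-zone movement: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hzmove infers whether a hybrid zone between two parapatric sister species has
moved along a one-dimensional transect, and whether the movement can be
explained by demography alone or requires directional (adaptive)
introgression. The package was built around a two-species white-pine system —
a southern species (here "species A"), a northern species ("species B") and a
broad admixed band between them — but every component is generic to
two-taxon hybrid zones sampled along a transect. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic-data tests do and do not establish.

## The geographic cline model

All spatial inference rests on the standard sigmoid cline. A response $p(x)$
(allele frequency, hybrid index, or trait mean) at transect position $x$ (km)
follows

$$p(x) = p_{\min} + (p_{\max}-p_{\min})\,
  \frac{1+\tanh\!\big(2(x-c)/w\big)}{2},$$

with centre $c$ (the inflection point, km) and width $w$ (the inverse of the
maximal slope, km). Outside an interval $[c-\delta_L,\,c+\delta_R]$ the
response may follow exponential tails, continuous with the core at the
junction:

$$p(x) = p_{\min} + \big(p(c-\delta_L)-p_{\min}\big)\,
  e^{\,4\tau_L (x-(c-\delta_L))/w}, \qquad x < c-\delta_L,$$

and mirrored on the right. $\tau \in [0,1]$ scales the tail decay relative
to the core slope; $\tau = 1$ gives a tail as steep as the core, small
$\tau$ a long shallow tail of introgressed alleles. This is the
HZAR-compatible convention; the tail formula matters because long tails are
exactly what introgression beyond a moving front produces.

The frequency model family crosses five tail modes (none, left, right,
mirror, independent) with three scalings of $p_{\min}/p_{\max}$ (fixed at 0
and 1; set to the observed extremes; estimated freely), 15 models. The
trait family estimates the asymptotes and varies only the tails, 5 models.
A no-cline null (constant response; 1 parameter for frequencies, 2 for
traits) is always available for comparison.

**Likelihoods.** Allele counts are binomial,
$k_i \sim \mathrm{Bin}(n_i,\ \tilde p(x_i))$ with $\tilde p$ clipped to
$[10^{-9}, 1-10^{-9}]$; trait and hybrid-index means are Gaussian,
$\bar y_i \sim N(p(x_i),\ s_i/\sqrt{n_i})$. Observations are population
records, so the AICc sample size is the number of populations; with 34
populations and up to 8 free parameters the small-sample correction is far
from negligible, which is why AICc rather than AIC.

**Fitting.** Replicate adaptive Metropolis–Hastings chains (Gaussian
random-walk proposals, scales tuned to a 20–40% acceptance window during
burn-in, flat priors on a bounded box: $c \in [-0.25L,\,1.25L]$ for transect
length $L$, $w \in (0,3L]$, $\delta \in [0,L]$, $\tau \in [0,1]$). Centres
beyond $L$ are deliberately inside the box: such fits are meaningful and are
excluded downstream as off-transect, not silently clamped. The MLE is the
best visited state refined by bounded quasi-Newton optimisation. The 95%
interval is the profile-likelihood 2 log-likelihood-unit (2-LLU) region:
for each reported parameter a grid spanning the visited range is profiled by
re-optimising the remaining parameters, with the binned chain maxima as a
floor, and the interval endpoints interpolated linearly. Profiling by
re-optimisation rather than by the raw chain alone was a deliberate choice:
the binned-chain profile systematically under-covers with practical chain
lengths, and the refinement costs little. Convergence across replicate
chains is flagged (spread of per-chain optima above 5% of the pooled 2-LLU
width), never enforced — short exploratory fits are still usable, just
marked.

**Model selection.** Minimum AICc wins, ties to fewer parameters. When the
null wins, the locus is excluded from centre-based analyses; a fitted centre
greater than the transect length likewise. Both exclusions are reported, not
dropped silently.

## Hybrid index and genomic clines

The hybrid index $h$ (proportion of species-B ancestry) is a supervised
maximum-likelihood estimate: allele dose at a diagnostic locus is
$\mathrm{Bin}(2,\ h\,p_B + (1-h)\,p_A)$ given parental reference frequencies,
maximised over $h \in [0,1]$, with a 2-LLU support interval from a grid
profile. This replaces model-based global admixture coefficients (Q-scores):
for a two-taxon system with known parental references the two are
operationally equivalent as cline input, and the supervised estimate is
orders of magnitude cheaper and deterministic.

Per-locus introgression is measured by the genomic cline function
$$\phi(h) = h + 2h(1-h)\big(\alpha + \beta(2h-1)\big),$$
clamped to $[0,1]$: $\phi$ is the probability of species-B ancestry at the
locus given genome-wide $h$; $\alpha$ shifts ancestry excess
(positive = excess species-B), $\beta$ steepens or flattens the transition.
Each locus gets an independent Metropolis–Hastings fit of $(\alpha, \beta)$
with $N(0, 0.5^2)$ priors — a deliberate simplification of the full
hierarchical Bayesian genomic-cline machinery, whose hierarchical variances
are not identifiable from a single data set of this size. Outliers are
declared by the 95% equal-tailed credible interval excluding zero. Both
parameters are estimated; only $\alpha$ is interpreted. Calibration checks
in the test suite verify ~95% coverage of $\alpha = 0$ and majority
detection of planted $\alpha = +0.5$.

## Ohta's D variance partitioning

Two-locus disequilibrium in a subdivided population is partitioned on gamete
frequencies $g_{ij}^{(k)}$ (subpopulation $k$), with unweighted
subpopulation means. The five components (within-subpopulation
$D^2_{IS}, D'^2_{IS}$; among-subpopulation $D^2_{ST}, D'^2_{ST}$; total
$D^2_{IT}$) satisfy $D^2_{IT} = D'^2_{IS} + D'^2_{ST}$ exactly under equal
weights — the identity is a test invariant at $10^{-10}$. The transect is
tiled into overlapping windows of four populations (overlap one; 34
populations give 11 windows), components are averaged over a seeded
subsample of locus pairs (default cap 50,000), and the reported profile is
the ratio of means $\bar D^2_{IS} / \bar D^2_{ST}$ — ratio of means rather
than mean of ratios because per-pair ratios are unstable when a pair's
among-population term is near zero; the alternative is available by flag.
A rising ratio toward one end of the zone is the classic signature of
recent introgression at an expanding front.

Phase matters: the components are gametic. Synthetic and simulated data
carry true haplotypes; for unphased empirical genotypes a two-locus EM
under random mating estimates gamete frequencies as a fallback. With 3–10
individuals per population the components carry a finite-sample noise floor
(of order $p^2q^2/2n$ per pair); profiles should be read comparatively
across windows, not as absolute LD levels.

## The individual-based simulator

The simulator re-implements, in minimal form, a spatially explicit
eco-genetic meta-population model: a one-dimensional column of patches in
three contiguous bands (species A south, hybrid middle, species B north),
monoecious random mating within patches, Poisson fecundity (expectation
capped so a full patch replaces itself), Mendelian transmission over
unlinked biallelic loci — gametes drawn as Bernoulli(dose/2) per locus,
which is exact for unlinked loci — dispersal, then density regulation
truncating to carrying capacity. There is no selection, no age structure,
and generations do not overlap.

Four phases reproduce two divergence histories. Phase I: the middle band is
closed; model A (secondary contact) has zero among-group dispersal, model B
(speciation with gene flow) keeps a small background species A–species B
exchange. Phase II: species A colonises the middle for a fixed number of
generations; the scenario regime then starts only once every middle patch
holds 50% of its capacity (checked each generation; the switch is
permanent). Phase III scenarios: (i) both parental groups exchange with the
hybrid band; (ii) only species B does; (iii) = (i) with rates halved
(model B only). Phase IV is common: hybrid–species B exchange only.

Parameter defaults had to be chosen rather than copied — the original
scenario parameterisation lives in supplementary material that is not
available — and are documented as assumptions: parental patches
K = 100, hybrid patches K = 50 (the hybrid band is more fragmented and
smaller), among-group dispersal 0.02 per offspring per enabled pair,
within-group adjacent-patch movement 0.15, background Phase-I exchange
0.001, fecundity 2. Because exact trajectories under the original
parameters are not reproducible, the tests assert ordering and stability
properties instead: drift alone makes among-group differentiation
($F_{CT}$) non-decreasing; Phase-III gene flow lowers $F_{CT}$ relative to
a zero-dispersal control; the scenario matching contemporary gene flow
(B.ii) keeps a stable fitted cline centre while unrestricted exchange (B.i)
displaces it. Hierarchical $F$-statistics come from a three-level nested
ANOVA on allele indicators (components summed across loci;
$F_{CT}$ = among-group share of total, $F_{ST}$ = among-population share
within groups), cross-checked in the tests against a brute-force
sums-of-squares oracle.

Cline-centre tracking fits the per-patch mean hybrid index with the
fixed-0/1 mirror-tail model at scheduled generations; shifts are reported
as percentages of the landscape extent.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume, so the
whole pipeline is testable without any external data: 34 populations
(5 species A, 16 hybrid, 13 species B) of 3–10 individuals along a
~2,000 km south-to-north transect; parental allele frequencies from a
Balding–Nichols model with dispersion `fst_noise`, a `frac_diagnostic`
subset pushed to near-fixation for alternative alleles; individual
admixture proportions Beta-distributed around a sigmoid ancestry cline; and
per-haplotype, per-locus Bernoulli ancestry draws (no recombination map —
the admixture LD that matters here comes from variance in individual
ancestry, not from linkage). Two Gaussian traits follow their own (wider,
optionally offset) cline: the offset is the planted hybrid-zone-movement
discordance. Raw trait scales are arbitrary and configurable; no published
raw trait moments exist to copy.

Optional planted structure supports end-to-end signature tests:

* *introgressed* loci get a genomic-cline boost $(\alpha, \beta > 0)$ —
  excess species-B ancestry concentrated at intermediate-to-high hybrid
  indices, clines that track the genome-wide (Q-score) centre;
* *retained* loci get the mirrored deficit (species-A alleles persisting
  against the gradient, $\alpha < 0$);
* *relict* loci cline at the (southern) historical centre — neutral
  laggards of a moved zone, the loci that make the morphological row of the
  contingency table;
* remaining diagnostic loci receive per-population ancestry jitter
  (`drift_concentration`) that scatters their fitted centres without
  giving them a systematic genomic-cline signal;
* north of the centre, an exponential ancestry tail plus a reduced Beta
  concentration (`front_concentration`) emulate the broad ancestry variance
  behind an expanding front — the source of the rising
  $D_{IS}\!:\!D_{ST}$ profile.

What passing these tests shows: the pipeline detects, end to end, a planted
centre discordance, a planted association between introgression direction
and geographic coincidence, and a planted front signature, at empirical
sample sizes. What it does not show: robustness to genotyping error,
missing-data structure, linked loci, or ascertainment bias in diagnostic-SNP
selection — none of which the generator emulates (sequencing artefacts are
out of scope by design).

## The contingency analysis

Each retained diagnostic SNP is classified by geographic coincidence
(centre within the Q-score 2-LLU interval; within the union of the trait
intervals; neither — after excluding null-model and off-transect fits) and
by genomic-cline class (positive / negative / none). Outlier classes may be
estimated in-pipeline or imported — the original analysis imported its
$\alpha$ calls from an earlier study of the same system, and the pipeline
supports both routes. The 3×3 table is tested by Pearson chi-square
(no continuity correction, df = 4, significance threshold 0.01), reported
with each cell's percentage contribution to the statistic and the sign of
its deviation — the contribution matrix, not the omnibus p-value, is what
identifies *which* association drives the result. A centre falling in both
the Q and morphological windows (possible only when those windows overlap)
goes to the nearer centre with a warning.

## Numerical choices and degenerate inputs

* Quantile convention for diagnostic-SNP selection: type-7 interpolation on
  $|\Delta p|$, ties kept (retention uses $\geq$). The exact convention used
  originally is unrecoverable; type-7 is R's default and the tie behaviour
  is stated rather than hidden.
* The 5-km morphological merge uses $\leq$ (boundary equality merges);
  radius configurable.
* The southernmost population is the minimum-latitude one, ties broken by
  minimum longitude; distances are haversine on a 6,371-km sphere.
* Window sets with a population count that does not tile exactly keep a
  truncated final window, flagged `partial`.
* Binomial likelihoods clip frequencies at $10^{-9}$; hybrid-index and
  genomic-cline probabilities at $10^{-9}$–$10^{-6}$ as appropriate; all
  clipping constants are visible in the code, not magic side effects.
* Monomorphic loci: skipped with warnings (genomic clines), undefined and
  flagged (F-statistics), excluded from LD windows (profiles).
* Every stochastic routine takes an explicit seed; replicate chains and
  replicate simulation runs use `seed + index`.

## Problem sizes used by the automated checks

The test suite and acceptance script run the full machinery at reduced but
honest scales, chosen so each stage's statistical claim is still testable:
cline recovery at 30 populations × 40 alleles with 10,000-step chains over
20 replicates; genomic-cline calibration at 100 loci × 200 individuals;
simulator properties at 10 patches per group, K = 50, 500 generations,
6 replicates; the end-to-end synthetic study at 34 populations and 1,000
loci (100 diagnostic). These sizes are the package's own test design;
scaling any of them up is a matter of configuration, not code.

## Known limitations

* Clines are one-dimensional; two-dimensional zones must be projected onto
  a transect first.
* The genomic-cline model is per-locus independent — no hierarchical
  shrinkage across loci, no linkage-aware modelling.
* The simulator has no selection, so it can only calibrate what demography
  alone produces; that is its purpose, not a bug, but it cannot simulate
  adaptive introgression itself.
* Ohta components from 3–10 individuals per population are noisy; profiles
  are comparative, and bootstrap bands (20 resamples by default) should
  accompany any empirical claim.
* The hybrid index assumes known, distinct parental reference frequencies;
  badly chosen references bias $h$ toward 0.5.
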