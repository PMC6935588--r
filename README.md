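# hzmove

Detecting and explaining the movement of a hybrid zone along a geographic
transect.

When two parapatric sister species meet and interbreed — the motivating case
is a pair of recently diverged white pines, a southern species and a northern
species joined by a broad admixed band — the zone where they exchange genes
can itself move. Movement leaves a characteristic three-part signature:

1. **Non-coincident cline centres.** The geographic cline of genome-wide
   ancestry (the hybrid index, or Q-score) is displaced relative to the
   clines of morphological traits that respond more slowly; the two centre
   estimates' confidence intervals do not overlap.
2. **Directional introgression.** Loci with excess ancestry from the species
   the zone is moving toward (positive genomic-cline α) are
   over-represented among SNPs whose geographic cline centres coincide with
   the (shifted) genome-wide centre.
3. **Elevated within-population LD at the front.** The ratio of within- to
   among-population components of two-locus disequilibrium
   (Ohta's D²_IS : D²_ST) rises toward the zone's expanding edge.

hzmove implements the full inference pipeline for this signature, plus a
forward simulator to calibrate what demography alone can produce:

* **Geographic clines** — sigmoid `p(x) = pmin + (pmax−pmin)(1+tanh(2(x−c)/w))/2`
  with optional exponential tails; binomial likelihood for allele counts,
  Gaussian for trait means; adaptive Metropolis–Hastings fitting, AICc model
  selection across the 15-model frequency family (5 tail modes × 3 scalings)
  or the 5-model trait family, comparison against a no-cline null, and
  profile-likelihood ±2 log-likelihood-unit (2-LLU) intervals.
* **Hybrid index and genomic clines** — supervised maximum-likelihood
  ancestry proportion per individual; per-locus Bayesian genomic-cline
  parameters `φ(h) = h + 2h(1−h)(α + β(2h−1))` with credible-interval
  outlier classes.
* **Ohta's D variance partitioning** — D²_IS, D²_ST (and primed variants,
  with the exact identity D²_IT = D′²_IS + D′²_ST) over 11 overlapping
  4-population windows along the transect, with neutral-locus bootstrap
  bands.
* **Individual-based simulator** — a patch-structured metapopulation run
  through four phases (divergence, colonization, scenario-specific gene
  flow, contemporary gene flow) under secondary-contact and
  speciation-with-gene-flow histories, with hierarchical F-statistics
  (F_ST, F_CT) and cline-centre tracking through time.
* **Contingency analysis** — 3×3 classification (geographic coincidence ×
  α-outlier class) with Pearson chi-square and per-cell percentage
  contributions.
* **Synthetic data** — a generator producing landscapes, phased genotypes
  and clinal traits with all of the structure above planted and known, so
  the entire pipeline is testable offline.

## Worked example

```r
library(hzmove)

# a synthetic hybrid zone: 34 populations, 3-10 trees each, 1,000 SNPs of
# which 10% are nearly diagnostic; ancestry cline centred at 1,250 km,
# trait clines lagging 400 km south
spec <- synthetic_spec(n_loci = 1000, cline_centre_km = 1250,
                       cline_width_km = 150,
                       trait_centre_offset_km = -400, seed = 1)
res <- run_pipeline(spec = spec, seed = 1, out_dir = "hz_out",
                    params = list(chain_len = 3000, burnin = 800,
                                  n_chains = 2))

res$q_fit
#> cline_fit [mirror.fixed01]: lnL = 91.153, k = 4, AICc = -172.926
#>   MLE: centre = 1251, width = 141.4, delta = 152.3, tau = 0.01591
#>   2-LLU centre: [1244, 1255]
res$trait_fits$cone_length$best$mle[c("centre", "width")]
#>   centre    width
#> 836.8078 705.8268
head(res$ohta[, c("midpoint_km", "ratio")], 6)
#>   midpoint_km ratio
#> 1     136.252 0.061
#> 2     415.653 0.068
#> 3     634.517 0.083
#> 4     802.504 0.078
#> 5     987.844 0.085
#> 6    1166.075 0.125
```

The hybrid-index cline centre (1,251 km, 2-LLU interval 1,244–1,255) sits
~415 km north of the cone-length centre (837 km): the planted movement
signature, recovered, with disjoint intervals. `res$contingency` holds the
3×3 table and chi-square contributions; `res$ohta` the D²_IS:D²_ST profile
per transect window, rising toward the hybrid zone from the south. The run
takes a few minutes at these chain lengths.

To ask whether demography alone could move the centre that far:

```r
cfg <- scenario_config(model = "B", scenario = "ii",
                       n_patches = c(speciesA = 10, hybrid = 10, speciesB = 10),
                       K = c(speciesA = 50, hybrid = 50, speciesB = 50),
                       phase_gens = c(I = 100, II = 20, III = 230, IV = 150))
out <- simulate_scenario("B.ii", n_replicates = 3, cfg = cfg, seed = 1)
out$summary          # mean ± SE of F_ST / F_CT per generation
relative_shift(centre_t = 1500, centre_ref = 1250, landscape_extent = 2000)
#> [1] 12.5   # percent of the landscape
```

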