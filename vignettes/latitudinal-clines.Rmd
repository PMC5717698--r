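---
title: "Methods: latitudinal clines, parallel architecture, and their calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latitudinal clines, parallel architecture, and their calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latcline)
```

# The scientific question

A species distributed along two replicated latitudinal gradients — two
diverged lineages, one per coast of an ocean basin — lets us ask whether
climate-associated selection acts in parallel. The package answers three
nested questions. First, *which* loci show steep monotone allele-frequency
change with latitude within each lineage? Second, is the number of loci
clinal in *both* lineages larger than chance would produce? Third, how does
the resulting north–south genetic structure relate to geography and climate?

# The cline model

Within one lineage, for one biallelic locus, let `k_j` be the count of the
counted allele among `m_j = 2 n_j` successfully genotyped allele copies in
population `j` at latitude `x_j`. The model is a binomial logistic
regression:

$$ k_j \sim \mathrm{Binomial}\!\left(m_j,\; p(x_j)\right), \qquad
   p(x) = \frac{1}{1 + e^{-(a + b x)}}. $$

Using the binomial count rather than the bare frequency is deliberate:
small rivers carry proportionally less information and should weigh less.
The classifier statistic is the **fitted range**
$\Delta p = |\,\hat p(x_{\max}) - \hat p(x_{\min})\,|$, the fitted curve
evaluated at the lineage's observed latitude extremes. Measuring the range
on the fitted curve rather than on raw endpoint frequencies makes the
statistic robust to a single noisy terminal population. A locus is **clinal**
when $\Delta p$ *strictly* exceeds the threshold (default 0.40) and the fit
either converged or hit the separation cap — a capped fit is a maximally
steep cline, not a failure. The logistic functional form already guarantees
a monotone sigmoid with exponentially decaying tails, so no separate shape
vetting is applied.

`threshold_scan()` supports the choice of cutoff descriptively: it counts
selected loci over a threshold grid and reports the knee — the grid point
maximizing the discrete second difference of the count curve, i.e. where the
count collapses fastest. The knee is a diagnostic; classification always
uses the configured threshold.

## Numerical choices

* IRLS with convergence tolerance `1e-8` and at most 100 iterations.
* Separation cap `|b| <= 50` per degree latitude. Exact complete separation
  (every population fixed, low-latitude fixed for one allele and
  high-latitude for the other) is detected up front; the slope is set to the
  cap, the intercept re-profiled at that slope, and the fit flagged.
* Fitted probabilities are clamped to `[1e-12, 1 - 1e-12]` inside the
  weighted least-squares step, and IRLS weights floored at `1e-12`.
* A locus monomorphic within a lineage gets a degenerate intercept-only fit
  with `dp = 0` — it cannot be clinal there by construction.
* Polarity is irrelevant: recoding the counted allele maps `p` to `1 - p`
  and leaves `dp` unchanged (tested as an invariance).

# Parallel architecture: the overlap test

With `n1` and `n2` clinal loci detected in the two lineages out of a common
panel of `N`, and `k_obs` loci clinal in both, `overlap_permutation()` draws
two uniform subsets of sizes `n1`, `n2` without replacement 100,000 times
and reports the fraction of draws whose intersection **strictly** exceeds
`k_obs`. The exact distribution of the intersection is
Hypergeometric(`N`, `n1`, `n2`), and `hypergeom_tail()` (log-gamma
arithmetic, exact to 12+ digits) is computed alongside every permutation run
as the analytic oracle. The strict-exceedance convention is the package
default because the inclusive tail `P(X >= k)` and strict tail `P(X > k)`
differ materially at these sizes (0.21 vs 0.12 at N = 1773, n1 = 84,
n2 = 195, k = 12); both are always reported so the convention is never
hidden.

# Population structure around the clines

* **Weir–Cockerham F_ST** (1984 estimator): per-locus variance components
  `a` (among populations), `b` (among individuals within populations), `c`
  (within individuals), with the multilocus estimate as the ratio of summed
  components — the standard convention, unbiased relative to averaging
  per-locus ratios. Negative per-locus estimates are retained for the same
  reason. Loci monomorphic over the groups are 0/0 and excluded from sums.
* **AMOVA** (two-level): squared-Euclidean distances between genotype
  allele-count vectors (missing genotypes mean-imputed per locus), variance
  components by nested ANOVA expectations with unequal sizes. F_CT is tested
  by permuting populations among groups, F_SC by permuting individuals among
  populations within groups; p-values use `(exceedances + 1) / (n_perm + 1)`.
  The allele-count distance is a declared convention, chosen because phased
  haplotypes are unavailable for SNP-array data.
* **Isolation by distance**: ordinary least squares of linearized F_ST,
  `F/(1-F)`, on pairwise distance over unordered pairs, significance by a
  one-sided Mantel permutation. Pairs at `F_ST = 1` linearize to infinity
  and are excluded with a warning.

# From clinal loci to a north–south divide

`dapc_membership()` reproduces the standard DAPC recipe at K = 2: mean
imputation of missing genotypes, centering, PCA, K-means on the retained
components (20 seeded restarts), then linear discriminant analysis on the
K-means groups, giving per-individual posterior memberships averaged to
population level. Averaging (rather than modal assignment) was an open
choice; it preserves within-river heterogeneity and makes the coefficient
continuous, which the downstream logistic models need. The number of
retained components defaults to those explaining 80% of variance, capped at
a third of the individuals — the usual DAPC overfitting guard; the retention
rule is a free parameter of the method and is recorded in the output.

`standardize_south_north()` maps any per-population coefficient (DAPC
membership, admixture Q from external software, spatial-PCA lagged scores —
the latter two enter through a plain CSV contract and are deliberately not
re-implemented) onto `[0, 1]`: the sign is flipped if the coefficient
correlates negatively with latitude, then min–max scaled. At exactly zero
correlation the orientation is chosen so the northernmost population sits at
or above the mean — an arbitrary but documented and deterministic tie-break.

The standardized coefficients are then modelled by `fit_logistic_cline()`
against one predictor at a time (latitude in degrees, distance from the
southernmost site in km, or a climate covariate): a two-parameter logistic
fitted by maximizing the Bernoulli-form quasi-likelihood on the continuous
responses. The reported quantities are the inflection point
`x* = -alpha/beta` (the predicted north–south divide, in predictor units),
AIC with 2 parameters, and McFadden's pseudo-r² `1 - logL/logL0` clamped to
`[0, 1]`. Treating continuous `[0, 1]` responses through the Bernoulli-form
likelihood is a quasi-binomial convention — the exact likelihood for such
coefficients is not uniquely defined — so AIC and pseudo-r² should be read
as rankings across predictors, not absolute goodness measures. Responses
exactly 0/1 are shrunk by `1e-6` except in the exactly-binary separated
case, which takes the capped-separation path. `compare_predictors()` ranks
by AIC, breaking ties by pseudo-r² and then name.

# Geography and environment

* **Least-cost marine distances**: water cells of a regular lat/lon grid
  form a graph with 8-neighbour connectivity and great-circle edge weights;
  Dijkstra shortest paths connect the cells nearest each river mouth. Land
  is impassable. River mouths must snap to water within 3 cells by default —
  an error otherwise, rather than a silent unlimited search, because a
  distant snap silently distorts the distance matrix. Grid resolution is a
  knob (0.1° default for real coastlines); the 8-neighbour metric
  overestimates great-circle distance by at most ~8% on open water, and
  tests bound it at 5% for near-diagonal routes. A synthetic coastline
  rasterizer (polygon land masses) supports tests without bathymetry data.
* **NMDS re-projection**: Kruskal stress-1 minimization (monotone regression
  on ranks, via vegan's engine) re-embeds the least-cost matrix in the plane
  for methods that need Cartesian coordinates; two dimensions because the
  downstream spatial analyses consume planar coordinates. Best of one
  metric-scaling start plus four random starts.
* **VIF pruning**: predictors are dropped iteratively, largest
  `1/(1 - R²)` first, until all are below 5. Among tied maxima the later
  column is dropped, so the earlier of two duplicated covariates survives —
  deterministic and order-faithful.
* **RDA**: population-level clinal-locus allele frequencies as the
  multivariate response (the population, not the individual, is the unit
  everywhere else in the pipeline, and frequencies are what the cline model
  fits), climate covariates as predictors, optionally conditioned on
  latitude and longitude. Global and marginal (type-III) significance by
  permutation of reduced-model response rows — the standard constrained-
  ordination scheme. Two degenerate situations are handled explicitly: full
  absorption of the predictors by the conditioning variables returns a
  zero-constrained result rather than an error, and an exactly saturated fit
  returns the minimal attainable p-value `1/(n_perm + 1)` because no
  permutation can exceed an unbounded observed statistic.
* **Partial Mantel**: correlation of off-diagonal residuals after matrix
  regression of each distance matrix on the control, permuting rows/columns
  of the first matrix jointly and re-residualizing. Two-sided by default
  (reported conventions vary across studies; two-sided is the
  conservative choice, and the one-sided variant is available). The engine
  is implemented in the package so the sidedness is controlled; vegan's
  independent implementation is used as a cross-check in the tests, never as
  the implementation.

# The synthetic-data generator

`simulate_dataset()` emulates the structure of a merged two-lineage SNP
survey: two lineages of 74 and 60 river populations (about 30 individuals
each, 1773 loci) spanning roughly 15° and 27° of latitude, lineage-level
drift at F_ST 0.110 and 0.089, clinal fractions 84/1773 and 195/1773 with
12 loci clinal in both lineages, inflection latitudes 53.3° and 59.9°,
climate covariates affine in latitude plus noise, and 5% missing genotypes —
the scale of the real surveys this pipeline addresses. Mechanics:

* **Neutral loci**: ancestral frequency π ~ Uniform(0.05, 0.95) per lineage,
  population frequencies Beta(π(1−θ)/θ, (1−π)(1−θ)/θ) — the Balding–Nichols
  model, chosen because its drift parameter θ *is* the expected F_ST, giving
  the estimator-recovery tests an analytic target.
* **Clinal loci**: logistic expectation in latitude between asymptotes 0.1
  and 0.9 (steepness 1.5° per logistic unit, random north-high or south-high
  orientation), with the same beta jitter at θ/4. The milder jitter keeps
  planted clines detectable and is an explicit knob, not a hidden constant.
* **Genotypes**: Binomial(2, p) per individual — Hardy–Weinberg within
  rivers; missingness i.i.d. All randomness flows from one seed; identical
  configs are byte-identical.

What the generator does *not* emulate — and what passing tests therefore do
not demonstrate about real data: linkage disequilibrium between loci,
ascertainment bias of SNP arrays (a real concern when comparing lineage
heterozygosities), secondary contact and admixture zones, isolation-by-
distance within lineages (drift is exchangeable across populations), and
uneven river sampling density. Clines generated by secondary contact rather
than selection would look identical to this generator and to the classifier;
distinguishing those causes requires demographic modelling outside this
package's scope.

# Calibration and problem sizes

The test suite checks, among others: classifier sensitivity ≥ 0.95 and
neutral false-positive rate ≤ 0.01 on panels of 60 populations × 30
individuals × 1000 loci with 5% planted clines of generating range 0.8 at
θ = 0.1 (10 seeds); inflection recovery within ±1° (median over 100 seeds of
30-population coefficient curves with noise SD 0.05); exact agreement of the
Weir–Cockerham components with an independent allele-indicator ANOVA oracle,
of Dijkstra distances with Floyd–Warshall on a toy raster, and of the
hypergeometric tail with full enumeration; and uniformity of Mantel, partial
Mantel, RDA and AMOVA permutation p-values under simulated nulls (200 seeds,
99 permutations each, rejection rate bounded by the 99% binomial interval
around 0.05). These sizes were chosen as the smallest that make the
statistical claims sharp; the generator's full default scale is exercised by
the pipeline example below them.

# Known limitations

* The cline classifier is marginal per locus: correlated loci (inversions,
  linked blocks) are counted as independent evidence in the overlap test.
* The fitted-range statistic saturates for loci fixed differentially at the
  range ends; all such loci look equally clinal regardless of steepness.
* AMOVA uses allele-count distances, not haplotypic distances.
* Least-cost paths use great-circle edge weights on cell centers; no
  ellipsoidal correction, no depth weighting.
* The quasi-binomial coefficient models report Wald p-values that are
  approximate for small numbers of populations; rank models by AIC instead.

# A compact end-to-end run

```{r pipeline, eval = FALSE}
cfg <- list(
  output_dir = tempfile("run"),
  seed = 1,
  simulate = list(lineages = c("w", "e"), n_pops = c(12, 12), n_ind = 15,
                  n_loci = 150, clinal_fraction = 0.1, n_shared_clinal = 4),
  overlap = list(iters = 10000),
  stats = list(n_perm = 99),
  envassoc = list(n_perm = 199))
manifest <- run_pipeline(cfg)
manifest
```

Every artifact in the manifest is a plain CSV or JSON file; rerunning with
the same config reproduces identical checksums.
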