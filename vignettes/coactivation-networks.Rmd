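---
title: "Brain-wide cFos co-activation networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-wide cFos co-activation networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofosnet)
```

## The analysis problem

Whole-brain immediate-early-gene mapping counts cFos-positive cells in
every atlas-defined region of every animal, producing an animal x region
table of counts. Because cFos expression marks recently active neurons,
regions whose activity rises and falls together across animals are
interpreted as functionally co-active. With cohorts of five or six
animals per genotype -- the realistic scale of cleared-brain light-sheet
studies -- the analysis must take small-sample statistics seriously at
every step.

`cofosnet` implements the full chain:

1. **Density normalization.** Counts are divided by region volume
   (cells/mm^3), so large structures do not dominate.
2. **Per-region group screening.** Shapiro-Wilk normality per group
   (reported, not used to switch tests), Welch's unequal-variance t per
   region, and one Benjamini-Hochberg correction across all testable
   regions jointly -- a single whole-brain family, not per-division
   families.
3. **Co-activation matrices.** Within each genotype, Spearman's rank
   correlation between every pair of regions across animals. Rank
   correlation is the right choice here: it is invariant to the
   monotone distortions that tissue clearing and detection efficiency
   introduce, and it is robust at n = 5-6 where Pearson is not.
4. **Thresholded adjacency.** A pair becomes an edge either when
   `|rho| >= tau` (effect-size mode, default `tau = 0.8`, *inclusive*:
   pairs at exactly the threshold count) or when its BH-adjusted
   permutation p over the family of all defined pairs is `<= alpha`
   (FDR mode). Both genotypes must use the same rule; mixing rules
   across groups would make density comparisons meaningless, so the fit
   refuses it by construction.
5. **Summaries.** Network density (edges over possible pairs), counts
   of surviving positive and negative correlations, a monotone
   threshold sweep (0.7, 0.8, 0.9 by default), and per-functional-network
   edge lists (social, salience, default-mode, lateral-cortical sets
   shipped as editable data files).

## Spearman's rho at n = 5-6: exact nulls and lattice values

For tie-free data the statistic is the closed form

$$\rho = 1 - \frac{6\sum_i d_i^2}{n(n^2-1)},$$

with $d_i$ the rank differences. At n = 5 the attainable values form the
lattice $\{1 - k/20\}$; at n = 6, $\{1 - k/35\}$ (even $k$). Values such
as 0.94285714, 0.88571429 and 0.82857143 in edge tables are exactly the
n = 6 lattice points for $\sum d_i^2 = 2, 4, 6$ -- a useful sanity check
on any pipeline run.

P-values:

* `n <= 9`, tie-free: the exact permutation null over all `n!` rank
  arrangements, enumerated once per `n` and memoised. At these sizes
  asymptotic approximations are not trustworthy; the exact null is
  cheap.
* `n > 9`, tie-free: the Edgeworth-corrected null distribution of
  $\sum d_i^2$ (the classical AS 89 expansion, evaluated through the
  routine R's own `cor.test` uses). The plain t approximation
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ is anticonservative deep in the
  tails -- at n = 40 it reports 3.9e-5 where the true permutation tail
  is 5.7e-5 -- and that error is exactly where FDR edge selection over
  ~19,000 region pairs operates. With the corrected null, measured
  false-discovery proportions match the BH guarantee.
* Tied data: average ranks with the t approximation, flagged per
  region. Ties arise in practice from integer counts in small-volume
  regions.

Regions constant across animals have undefined correlations; their rows
and columns are `NA`, they are flagged, and they can never contribute
edges. When two genotypes are compared after "adjusting for the number
of regions", both matrices are restricted to the regions defined in
*both* groups (`restrict_to_common_regions()`); this is an
interpretation of region-count adjustment -- restriction to a common
defined set -- and is labelled as such.

## The synthetic cohort generator

No public cFos count tables accompany studies at this scale, so the
package ships a generator whose output stands in for them in every test.
It is first-class, tested code, not a fixture.

Latent per-animal region vectors are drawn from a Gaussian copula.
Planted correlation blocks specify a target *Spearman* correlation
`rho*`; because a bivariate Gaussian with Pearson correlation $r$ has
population rank correlation $\rho_S = (6/\pi)\arcsin(r/2)$, the
generator inverts this ($r = 2\sin(\pi\rho^*/6)$) so that what you
plant is what the rank estimator should recover. Marginals are
log-normal densities, $\exp(\mu_j + \sigma_j Z)$ times a per-region,
per-genotype effect multiplier; counts are `round(density x volume)`.
Both representations are kept: the integer counts (what an acquisition
pipeline emits) and the continuous pre-rounding densities
(`latent_density_matrix()`), because count quantization introduces rank
ties in low-volume regions that are an artifact of rounding, not of the
biology, and planted-structure recovery is properly assessed tie-free.

Defaults are the study conditions the package targets: two genotypes at
n = 6 (WT) and n = 5 (KO), 196 regions, baseline density 300 cells/mm^3,
and log-scale dispersion 0.4 (a coefficient of variation near 42%,
typical of between-animal cFos variability; chosen once, on biological
grounds). `preset_cohort_spec()` adds the qualitative contrast the
package demonstrates end to end: a VTA density increase (x1.6) in the
knockout, planted salience-network co-activation in the wild type, and
denser planted default-mode co-activation in the knockout.

Two generator details worth knowing:

* When two blocks of one genotype cover the same pair, the larger
  target wins. Strongly overlapping near-unit blocks can imply a
  non-positive-definite latent correlation; the generator then stops
  with an error suggesting smaller `rho*` or smaller blocks (the preset
  uses disjoint blocks for this reason).
* Identical specs (including the seed) produce bit-identical cohorts.

What the generator does *not* emulate: spatial structure within
regions, detection false positives/negatives, registration error,
hemispheric asymmetry, or any dependence between behavior and counts.
Passing tests therefore certify the statistical machinery under a known
truth, not the acquisition pipeline.

The behavior side has its own generator: an alternating-renewal
zone-occupancy stream (exponential sojourns, `bout_rate` cycles per
second, default 1/30) whose realized zone-time fractions converge to a
requested profile. Degenerate profiles (a single zone filling the whole
trial; no scored zones) produce the obvious degenerate traces.

## Behavioral indices

All indices consume zone-occupancy event streams, not coordinates --
the interaction zone is a tracking-software construct, and abstracting
it keeps the module testable. Implemented: sociability and
social-novelty preference `(T_a - T_b)/(T_a + T_b)`; Y-maze spontaneous
alternation (three consecutive visits covering all three arms, over
visits minus two); elevated-plus-maze open/closed time ratio (open over
*closed*, not open over total); zone times, entries, latencies,
time-binned occupancy (default 60 s bins, a conventional choice);
longest bout within a window; and one-sample t tests of indices against
a null mean (0 for the signed indices; 1 is the natural null for a
trial-1/trial-2 familiarity ratio, which is how a "preference against a
hypothetical mean of one" is interpreted here).

## Numerical and design choices

* **Inclusive thresholding** (`>=`): edge tables in this field print
  pairs at exactly `rho = 0.8` under an `|rho| >= 0.8` rule; the
  implementation follows the data convention, and nestedness of edge
  sets across the sweep is asserted in tests.
* **Welch, not Student:** fractional degrees of freedom (e.g. 8.909 for
  6 vs 5 animals) are what unequal-variance tests of real cohorts
  report; df always lies in `(min(n1,n2)-1, n1+n2-2]`.
* **One FDR family:** all testable regions jointly. Regions constant in
  both groups are excluded from the family and logged, never silently
  assigned q = 1.
* **No normality-triggered branching:** Shapiro-Wilk results are
  reported next to the t results; the pipeline does not switch to rank
  tests on failure, because silent branching makes analyses
  irreproducible across cohorts.
* **Determinism:** every stochastic function takes a seed;
  `run_pipeline()` re-run from its written YAML config reproduces all
  numeric outputs byte for byte, and the JSON report carries the config
  hash.

## Problem sizes used by the test suite

The suite's Monte-Carlo sizes are chosen to make the asserted bounds
statistically meaningful at interactive runtimes: 200 null cohorts for
type-I calibration, 100 cohorts of n = 40 for planted-block recovery
(sensitivity and false-discovery proportion of FDR edge selection), 50
preset cohorts for the genotype density contrast, exhaustive
enumeration of all 120 rank permutations at n = 5, and 500 sampled
permutations at n = 6. The whole suite runs in about half a minute.

## Known limitations

* Welch's t at n = 6 vs 5 does not achieve its nominal size on skewed
  data: on the generator's log-normal densities its true type-I rate is
  about 0.038 at a nominal 0.05 (about 0.046 even on exactly normal
  data). This mild conservatism is a property of t-family tests at
  these sample sizes, and the calibration test reports it honestly
  rather than hiding it.
* Count-derived densities carry rank ties in small regions; tied pairs
  fall back to the t approximation for p-values. Use
  `latent_density_matrix()` for tie-free methodological experiments.
* Network comparison is descriptive: the package deliberately provides
  no permutation test for WT-vs-KO density differences, no community
  detection, and no hub/centrality statistics.
* The shipped 196-region catalogue is synthetic (plausible acronyms and
  divisions; placeholder volumes) so that analyses are runnable and
  testable out of the box; real studies should supply their own region
  table via `load_region_table()`.
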