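---
title: "Endpoint-fluorescence genotype calling and platform comparison: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endpoint-fluorescence genotype calling and platform comparison: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpplate)
```

## The data model

Endpoint (post-PCR) SNP genotyping reads two allele-specific reporter
fluorescence values per well. Plotting wells of one assay in the
`(signal_x, signal_y)` plane — allele-1 reporter against allele-2
reporter — yields up to three genotype clusters plus a background cloud:
allele-1 homozygotes (A11) near the horizontal axis, allele-2
homozygotes (A22) near the vertical axis, heterozygotes (A12) along the
diagonal, and the no-template controls (NTCs) near the origin. All
geometry in this package is *anchored on the NTC centroid*
$(\bar x_{NTC}, \bar y_{NTC})$, the mean signal of the assay's NTC
wells: background level varies between assays and platforms, and the NTC
is the only origin observable on every plate.

Three statistics summarize how well a platform discriminates alleles.
With $\Delta x = x - \bar x_{NTC}$ and $\Delta y = y - \bar y_{NTC}$:

* **Separation angle** $\alpha = \tan^{-1}(\Delta y / \Delta x)$, the
  angle between the X axis and the NTC-to-point ray, in radians. We
  evaluate it with `atan2`, which extends the plain arctangent to
  $\Delta x = 0$ (an on-axis A22 point) and agrees with it exactly for
  $\Delta x > 0$; deltas below $10^{-12}$ in magnitude are floored to
  zero and the result is clamped to $[0, \pi/2]$, since genotyping
  signal lies in the first quadrant relative to the NTC. A smaller A11
  angle means the homozygote cluster is better separated from the
  heterozygote diagonal.
* **NTC distance** $D = \sqrt{\Delta x^2 + \Delta y^2}$, proportional to
  fluorescence gain; longer is better (more headroom between signal and
  background).
* **Compactness** $S$, the sample standard deviation (divisor $n-1$) of
  the member-to-centroid Euclidean distances of a cluster. Tighter
  clusters give smaller $S$; $S$ is undefined (`NA`, never 0) for
  clusters with fewer than two members. The statistic is deliberately
  the SD *of distances*, not a 2-D dispersion: it is invariant to the
  cluster's orientation and matches how genotyping QC is done in
  practice.

Angle is scale-free; distance and compactness scale linearly with the
signal units, and all three are invariant under a joint translation of
points and NTC. The test suite asserts these equivariances explicitly.

## The allele caller

Instrument vendors ship proprietary auto-callers; `snpplate` instead
documents its own three-stage caller (`call_assay()`), run independently
per assay × platform so that every threshold adapts to that assay's own
scale. Let $d_i$ be well $i$'s NTC distance and $q_{90}$ the 90th
percentile of the $d_i$ over the assay's non-NTC wells.

1. **FAILED.** Wells with
   $d_i \le \max(m \cdot s_{NTC},\; f \cdot q_{90})$ are unamplified,
   where $s_{NTC}$ is the RMS distance of the NTC wells from their
   centroid, $m$ = `failed_radius_mult` (default 3) and $f$ =
   `failed_floor_frac` (default 0.05). The absolute floor matters: with
   the customary two NTC wells per assay, $s_{NTC}$ is half the distance
   between two background draws, a badly downward-biased estimate of the
   background scale. Writing background noise as $\sigma$, the distance
   of a dropout well from the *estimated* NTC centroid is
   Rayleigh$(\sigma\sqrt{3/2})$ while $3 s_{NTC}$ is
   $1.5\times$Rayleigh$(\sigma\sqrt2)$, and the probability the first is
   below the second is exactly $0.75$ — i.e. the multiplier rule alone
   misses a quarter of true dropouts, at any noise level. A floor of 5%
   of $q_{90}$ (a few multiples of typical background scatter, far below
   genotype-cluster radii) restores dropout recovery without touching
   genuine calls.
2. **INVALID.** Remaining wells with $d_i < 0.25\, q^{amp}_{90}$
   (`invalid_radius_frac`, with $q^{amp}_{90}$ the 90th percentile over
   amplified wells) produced signal but too little of it to classify —
   the "invalid" class of endpoint genotyping.
3. **Genotypes.** Remaining wells are clustered by k-means ($k = 3$) in
   $(\alpha_i, \log d_i)$ — angle is the discrimination axis, the
   log-radius separates genuine clusters from stragglers and makes the
   feature scale-free. Initialization is fixed (centroids at 15°, 45°,
   75° at the observed median log-radius), so calling is deterministic
   and independent of row order; a small Lloyd loop is used so that
   empty clusters are handled gracefully. Clusters with fewer than two
   members are merged into their angular neighbour (a diversity panel of
   inbred lines can lack heterozygotes entirely, and a spurious 3-way
   split must not invent them). Surviving clusters are labelled
   A11/A12/A22 by ascending mean angle (three clusters) or by nearest
   reference angle (fewer). Assays with fewer than three amplified wells
   are flagged uncallable and their amplified wells set to INVALID.

**Call quality** is the posterior probability of the assigned component
under an isotropic Gaussian mixture fitted to the final clusters in the
fluorescence plane (weights $n_k/N$, per-cluster $\sigma_k$ from the
mean squared centroid distance, with a relative floor of
$10^{-9} q_{90}$ so that noiseless clusters give quality 1). It is the
transparent analogue of the vendor "call quality" scores: near 1 deep
inside a cluster, falling towards 1/2 on a two-cluster boundary.
`min_quality` (default 0) optionally demotes low-posterior calls to
INVALID.

The caller is invariant under rescaling both channels by any $c > 0$
(all thresholds are relative), and a point exactly at the NTC centroid
is always FAILED.

## Platform comparison

`anova_crd()` implements the one-way fixed-effects decomposition under a
completely randomized design, computed directly from group means
($SS_B = \sum_g n_g(\bar y_g - \bar y)^2$, $SS_W$ by residual sum of
squares, $F = MS_B/MS_W$ on $(k-1, N-k)$ df). Degenerate inputs follow
explicit contracts: identical group means give $F = 0, p = 1$; zero
within-group variance with distinct means gives $F = +\infty, p = 0$ (a
noiseless simulation exercises this path). The implementation is
cross-checked in the tests against `lm()`/`anova()` on random data to
$10^{-8}$ relative error, and its type-I error at $\alpha = 0.05$ is
verified by 10,000-replicate null simulation.

**Replication unit.** Call quality is observed once per successful
amplification, so its ANOVA uses *per-point* replication (thousands of
df). The geometric metrics are properties of an assay's cluster, so
their ANOVAs use *per-cluster* replication by default (one observation
per assay × platform × label; tens of df) — using per-point values there
would pseudo-replicate within-cluster noise. Both units are available
via the `unit` switch in `summarize_clusters()` /
`compare_platforms()`; under `per_cluster` the angle and distance are
evaluated at the cluster centroid, under `per_point` they are pointwise
averages (arithmetic means are appropriate: angles live in
$[0, \pi/2]$, far from wrap-around, so circular statistics are
unnecessary). By convention angle and compactness comparisons are
restricted to the A11 cluster (`a11_only = TRUE`), while NTC distance
uses all called clusters.

**LSD letters.** `lsd_letters()` uses the pairwise Fisher threshold
$t_{1-\alpha/2, df_W}\sqrt{MS_W(1/n_i + 1/n_j)}$, which accommodates the
unequal group sizes that unequal dropout produces. Letters are assigned
one per *maximal clique* of the pairwise non-significance relation,
ordered by descending mean: two platforms share a letter exactly when
their difference is within their pairwise LSD. (The common
descending-mean sweep is the special case where non-significance is
interval-shaped; the clique formulation keeps the letters exact under
imbalance.) No multiplicity correction is applied across the four
metrics; the report says so.

**Concordance** between two platforms is the agreement fraction over
sample × assay cells genotype-called (A11/A12/A22) on *both* platforms;
FAILED/INVALID cells enter neither numerator nor denominator, and
heterozygote-vs-homozygote disagreements are discordant (strict
matching).

## The cost model

`cost_per_reaction()` divides the price of the minimum orderable amount
of each consumable (assay mix, master mix) by the number of reactions it
supports and sums the two, at a 5 µl reaction volume; DNA-extraction
cost is excluded. Values are reported raw and rounded half-up to the
cent (commercial rounding — `round()`'s banker's rounding would turn
0.405 into 0.40); `rank_platforms()` always ranks on the raw values, so
rounding can never reorder platforms.

## The synthetic plate generator

No public per-well fluorescence dataset exists for a three-platform
genotyping comparison, so `simulate_experiment()` generates one with the
statistical structure the analysis assumes, plus ground truth, making
every downstream stage testable end to end.

Model: per assay, genotype frequencies come from the per-assay allele-2
frequency under either Hardy–Weinberg or a fixed heterozygote fraction;
the genotype of a sample × assay is drawn once and shared by all
platforms (it is a property of the DNA, not of the chemistry), while
amplification outcome and fluorescence are platform-specific, drawn from
deterministic per-platform substreams of the single seed. Called wells
are isotropic Gaussian around a centroid at polar coordinates
$(r_g \cdot \text{gain}, \theta_g)$ from the NTC centre, with
$r_{A11} = r_{A22} = 1$ and $r_{A12} = 1/\sqrt2$ (so the heterozygote's
per-channel signal is comparable to a homozygote's single channel).
Failed wells are draws from the NTC background; invalid wells sit at the
genotype's own angle at a radius uniform between $2\,\sigma_{NTC}$ and
$0.25 \cdot \text{gain}$ — amplified, but in the dim zone below the
genotype clusters (placing them on the genotype ray, rather than at a
uniform angle, reflects that they are under-amplified true signal).

The three-platform reference scenario
(`default_three_platform_config()`) emulates a 94-sample + 2-NTC,
29-assay comparison of rhAmp, KASP and TaqMan (2,784 wells per
platform). Its fixed parameter choices, in units of normalized
fluorescence:

| parameter | rhAmp | KASP | TaqMan | rationale |
|---|---|---|---|---|
| gain | 5.01 | 1.51 | 1.93 | benchmark NTC-to-cluster distances of these chemistries (rhAmp ≫ TaqMan > KASP) |
| A11 angle (rad) | 0.19 | 0.19 | 0.35 | benchmark A11 separation angles; A22 mirrored, A12 = π/4 |
| noise_sd | 0.20 | 0.10 | 0.055 | reproduces the compactness *ordering* (TaqMan tightest, rhAmp loosest) at per-point noise levels consistent with callable clusters |
| fail rate | 3% | 6.5% | 7% | benchmark unamplified-sample rates |
| invalid rate | 7/2784 | 13/2784 | 57/2784 | benchmark invalid-call counts |
| ntc_sd | 1.5% of gain | — | — | NTC wells are background-only and tight relative to signal |

Benchmark compactness values aggregate assay-to-assay geometry variation
that the generator does not model (per-assay centroid-angle jitter
exists as an option, `angle_jitter_sd`, but defaults to 0), so planting
them directly as per-point noise would overstate within-cluster scatter;
only their ordering is planted. Heterozygote model: `fixed_fraction`
with 5% heterozygotes (a wheat diversity panel is essentially inbred);
per-assay allele-2 frequency uniform on (0.15, 0.5), keeping both
homozygote clusters populated as in a marker panel pre-selected for
polymorphism.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: PCR kinetics and cycle-by-cycle
amplification; probe thermodynamics and assay-design failure;
non-Gaussian, skewed or rotated clusters; plate-position and edge
effects; cross-contamination of NTC wells; sample-specific amplification
covariance across assays. Absolute concordance and call-quality values
from the simulation are therefore optimistic relative to field data; the
qualitative platform contrasts (orderings, letter patterns) are what the
scenario is designed to reproduce.

## Numerical and design choices

* Angles in radians everywhere; the CLI `--degrees` flag converts for
  display only.
* Tiny deltas ($<10^{-12}$) floored before angle computation; angles
  clamped to $[0, \pi/2]$.
* Plate CSVs serialize signals with 17 significant digits, so
  write → read round-trips are bit-exact; missing quality is an empty
  field, read back as `NA`.
* k-means ties (equidistant centers) resolve to the lowest-angle
  center; all iteration is deterministic.
* Per-platform simulation substreams are derived from the master seed as
  `(seed + 10007·i) mod (2^31 − 19)`, keeping seeds in integer range
  while decoupling platforms.
* ANOVA drops non-finite observations (e.g. `NA` compactness of
  singleton clusters) before decomposition and refuses groups with
  fewer than two observations, naming the offending group.

Problem sizes used by the test and acceptance suites (chosen as the
smallest sizes at which the statistical assertions are stable): the full
reference scenario (3 × 2,784 wells) for caller fidelity and the
qualitative pattern checks; 10,000 null replicates for ANOVA type-I
calibration; 200 seeded replicates of a two-platform, 4-assay, 40-sample
scenario for power/parameter recovery; 50 random datasets for the
linear-model equivalence check.

## Known limitations

* The caller assumes at most three genotype clusters per assay; copy
  number variants, null alleles and multi-allelic sites are out of
  scope.
* Cluster labels are angle-ordered, which presumes the allele-1 reporter
  is on the X channel; swap the channels before calling if an export
  reverses them.
* LSD controls the per-comparison error rate only; with many platforms,
  users wanting family-wise control should lower `alpha` themselves.
* The cost model covers consumables only (no DNA extraction, labour,
  instrument amortization or volume discounts) and does no currency
  conversion.
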