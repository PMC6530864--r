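# snpplate

Small-scale, targeted SNP genotyping on endpoint-fluorescence platforms
(TaqMan, KASP, rhAmp and similar two-reporter chemistries) produces, for
every well, one fluorescence value per allele-specific reporter. After
PCR the wells of an assay form clusters in the two-channel plane: the
allele-1 homozygotes (A11) lie near the X axis, the allele-2 homozygotes
(A22) near the Y axis, heterozygotes (A12) along the diagonal, and the
no-template controls (NTCs) near the origin. `snpplate` turns those raw
per-well tables into genotype calls and platform-comparison statistics —
the toolchain a breeding or genotyping lab needs to decide *which*
chemistry to adopt.

The package provides:

* a documented, deterministic **allele caller** anchored on the NTC
  centroid (background/FAILED radius, low-fluorescence/INVALID radius,
  then angle-ordered k-means with a Gaussian-mixture posterior as the
  call quality);
* the three standard **cluster-geometry metrics**, all measured from the
  NTC centroid `(x₁, y₁)` with `Δx = x₂ − x₁`, `Δy = y₂ − y₁`:
  - separation angle `α = tan⁻¹(Δy/Δx)` (radians),
  - NTC-to-point distance `D = √(Δx² + Δy²)`,
  - cluster compactness `S` = sample standard deviation of the
    member-to-centroid distances;
* **platform comparison**: one-way completely-randomized-design (CRD)
  ANOVA per metric, taking each successful amplification (or each assay
  cluster) as a replication, with Fisher LSD letter groupings
  (`LSDᵢⱼ = t₁₋α/2,df · √(MSE(1/nᵢ + 1/nⱼ))`) and cross-platform
  genotype concordance over jointly-called cells;
* a **cost model** (minimum orderable assay-mix + master-mix kit, price
  divided by reactions supported);
* a seeded **synthetic plate generator** that reproduces the statistical
  structure of a 94-sample + 2-NTC × 29-assay experiment on three
  platform profiles, with ground-truth genotypes and outcomes, so the
  entire pipeline is testable without instrument exports.

## Worked example

```r
library(snpplate)

exp   <- simulate_experiment(default_three_platform_config(seed = 1))
calls <- call_plate(exp$points)
call_rate_summary(calls)
#>   platform_id n_points n_called n_invalid n_failed failed_pct amplified_pct
#> 1        KASP     2726     2533        12      181   6.639765      93.36023
#> 2       rhAmp     2726     2620         3      103   3.778430      96.22157
#> 3      TaqMan     2726     2465        53      208   7.630227      92.36977

cmp <- compare_platforms(exp$points, calls)
cmp$anova$angle
#> One-way CRD ANOVA: cluster separation angle (rad)
#>           Df  Sum Sq   Mean Sq F value    Pr(>F)
#> platform   2 0.48860 0.2442982    1842 4.205e-70
#> residuals 84 0.01114 0.0001326      NA        NA
cmp$lsd$angle
#> LSD mean separation (alpha = 0.05): cluster separation angle (rad)
#>             mean  n group
#> TaqMan 0.3494839 29     a
#> rhAmp  0.1925516 29     b
#> KASP   0.1885472 29     b
#> LSD (mean group size): 0.006014

rank_platforms(default_cost_specs())
#>   platform_id cost_raw cost_rounded
#> 1       rhAmp  0.11898         0.12
#> 2        KASP  0.15109         0.15
#> 3      TaqMan  0.40650         0.41
```

Reading the output: each platform contributes 2,726 non-NTC wells (94
samples × 29 assays); TaqMan drops the most wells and rhAmp the fewest.
The angle ANOVA compares the 29 per-assay A11 cluster angles per
platform: TaqMan's allele-1 cluster sits at a significantly wider angle
(letter `a`) than rhAmp and KASP, which are statistically
indistinguishable (shared letter `b`). The cost table shows the
per-5-µl-reaction price of the minimum orderable kits, cheapest first.

`plot_discrimination(exp$points, calls)` draws the standard
allele-discrimination scatter, one panel per platform.

A command-line driver with subcommands `simulate`, `call`, `metrics`,
`compare`, `cost` and `report` is installed at
`system.file("scripts", "snpplate", package = "snpplate")`.

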