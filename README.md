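# diamorph

Regional morphometry of striated muscle from confocal fluorescence
microscopy, built for studies of the dystrophic (mdx) mouse diaphragm.

Dystrophin-deficient diaphragm remodels non-uniformly: fibrosis, fiber
branching, atrophy, regeneration and inflammation progress at different
rates in the dorsal, midcostal and ventral regions and at different ages.
`diamorph` quantifies that remodeling with six image-derived metrics and
compares cohorts across every genotype × age × region permutation:

| metric | image type | method |
|---|---|---|
| modal sarcomere length (μm) | longitudinal, α-actinin | band-pass-filtered 2D FFT: strongest spectral bin with period in [1.5, 4.5] μm |
| interstitial-space ratio | longitudinal | mean gap width ÷ mean fiber width along a line orthogonal to the fibers |
| % branched (Y) fibers | longitudinal | skeleton junctions with ≥3 limbs ≥5 μm, daughter pair ≤150° |
| fiber CSA (μm²) | cross-section, laminin | enclosed-interior labeling, shared walls split at the midline |
| % centrally nucleated (regenerating) fibers | cross-section, nuclei | nucleus centroid at normalized boundary distance ≥ 0.4 |
| macrophage density (per mm²) | cross-section, nuclei + CD68 | CD68 components overlapping a nucleus by ≥30% of the smaller |

Group comparisons use Welch t tests adjusted per metric by the step-down
Šidák (Holm–Šidák) procedure, `p_(i) → max monotone of 1 − (1 − p_(i))^(m−i+1)`,
at α = 0.05. A seeded synthetic-image generator (striation fields,
Voronoi cross-sections, truncated-normal cohorts) provides exact ground
truth for every stage, so the whole pipeline is testable without a
microscope.

## Worked example

```r
library(diamorph)

# 1. a noisy synthetic striation image with known 2.5 um banding
img <- generate_striation_image(striation_spec(
  period_um = 2.5, pixel_size_um = 0.1, noise_sd = 0.2,
  gap_to_fiber_ratio = 0, fiber_width_um = 60, seed = 1))$image
estimate_sarcomere_length(img)
#> <sarcomere_estimate> modal length 2.498 um (f = 0.4004 cyc/um, bin 0.009766), axis 0.0 deg

# 2. a synthetic cross-section: 40 fibers of mean CSA 500 um^2,
#    25% centrally nucleated, macrophages at 300 / mm^2
sec <- generate_cross_section(cross_section_spec(
  n_fibers = 40, csa_mean_um2 = 500, central_nucleus_fraction = 0.25,
  macrophage_density_per_mm2 = 300, seed = 1))
section_report(sec$image)
#> <section_report> 40 fibers, mean CSA 499.5 um^2, 25.0% regenerating, 4 macrophages (156.2 / mm^2)

# 3. cohort simulation from the study's reported group means + Holm-Sidak
tab <- sample_cohort(cohort_spec(default_group_parameters(), n_per_group = 6, seed = 1))
cmp <- compare_all(tab)
cmp[cmp$group_a == "mdx:pooled", c("metric", "mean_a", "mean_b", "adjusted_p", "significant")]
#>                       metric  mean_a mean_b adjusted_p significant
#> 1                    csa_um2 583.147 547.54   1.00e+00       FALSE
#> 2         interstitial_ratio   0.288   0.11   3.28e-12        TRUE
#> 3 macrophage_density_per_mm2 383.141  63.41   0.00e+00        TRUE
#> 4           percent_branched  14.981   2.61   2.43e-08        TRUE
#> 5       percent_regenerating  14.912   2.64   1.85e-12        TRUE
#> 6        sarcomere_length_um   2.528   2.64   1.00e+00       FALSE

# 4. the largest regional percent difference in three-month mdx macrophages
regional_spread(c(dorsal = 256.08, midcostal = 519.81, ventral = 210.17))
#> [1] 147.3284
```

The modal length lands within one frequency bin of the construction period;
the section report recovers the planted fiber count, mean CSA and central
fraction exactly (the macrophage count is a Poisson draw at the requested
density); at n = 6 images/group the fibrosis, branching, regeneration and
inflammation contrasts are already significant after family-wise correction
while the small sarcomere and CSA effects are not; and the regional
macrophage spread is 147%.

A full generate → measure → compare → report run is one call:

```r
run_pipeline(system.file("extdata", "demo-config.json", package = "diamorph"))
```

writing `metrics.csv`, `summary.csv`, `comparisons.csv`, mean±SD panels and
a `manifest.json` with every default and checksum. The same stages are
scriptable via `inst/scripts/diamorph` subcommands
(`run`, `generate`, `sarcomere`, `longitudinal`, `section`, `stats`, `report`).

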