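# cordmapper

Quantitative comparison of spinal interneuron soma distributions between
genotypes or experimental conditions, for developmental neurobiologists who
digitize cell positions from transverse spinal-cord sections.

## The problem and the method

Interneuron populations (dI1–dI6 and their subsets) settle at stereotyped
dorso-ventral (DV) and medio-lateral (ML) positions. To compare positions
across embryos whose sections differ in size, each soma's polar measurement —
distance *D* and angle *α* (degrees, from the horizontal axis through the
ventral-most midline point) — is normalized by the section's height *H*
(ventral-most to dorsal-most point) and hemicord width *W* (central canal to
lateral edge):

    DV = D · sin α / H        ML = |D · cos α| / W

The absolute value folds both hemisections onto one positive hemicord. The
resulting coordinates are dimensionless, so pixel and micron data mix freely.

Cells pooled across sections and embryos form one 2D sample per population ×
condition × axial level. Two conditions are compared with the **two-sample
Hotelling's T²** — the two-dimensional generalization of Student's *t*:

    T² = (n₁n₂)/(n₁+n₂) · (x̄₁−x̄₂)ᵀ S⁻¹ (x̄₁−x̄₂),
    F  = T² · (n₁+n₂−p−1) / (p(n₁+n₂−2))  ~  F(p, n₁+n₂−p−1)

with *S* the pooled unbiased covariance and *p* = 2. A seeded permutation
test provides an assumption-free companion p-value. Around the test sit 1D
Gaussian-kernel density profiles per axis and 2D density maps, per-embryo
cell-count summaries (mean ± SEM, Student's *t* or Mann–Whitney *U*), marker
co-labeling proportions, and ROI-based in-situ-hybridization intensity with
background subtraction (fixed 13,500 px² signal ROI by default).

A synthetic-data generator (truncated Gaussian-mixture positions, log-normal
section geometries, Poisson cell counts, ISH-like images) retains its ground
truth so every stage is verifiable by parameter recovery and calibration
studies without any imaging data.

## Worked example

Simulate a control/mutant pair in which the dI3 population is shifted 0.1
ventrally, then run the comparison:

```r
library(cordmapper)
truth <- cord_preset("dI3")
pair  <- shifted_pair(truth, c(-0.1, 0), n_embryos = 3, sections_per_level = 5,
                      levels = "thoracic", groups = c("control", "mutant"),
                      seed = 42)
norm    <- normalize_positions(pair$cells, pair$sections)
samples <- pool_samples(norm, by = c("population", "group", "axial_level"))
compare_distributions(samples[["dI3|control|thoracic"]],
                      samples[["dI3|mutant|thoracic"]],
                      n_perm = 999, seed = 1)
```

```
Distribution comparison: dI3, thoracic level (control vs mutant)
Two-sample Hotelling's T-squared test
  T2 = 226.9, F = 113.4 on df (2, 1200), p = 8.051e-46
  n = 554 vs 649 cells; centroid shift (b - a) = (-0.0928, -0.01065)
  note: cells pooled across sections/embryos are treated as independent
   observations (pseudoreplication caveat); embryos per group: 3 vs 3
  permutation p = 0.001 (999 permutations, seed 1)
  verdict at alpha = 0.05: significant
```

The centroid shift estimate (−0.093 in DV) recovers the generated −0.1 shift;
the permutation p-value agrees with the F approximation. Count comparisons
print equally directly:

```r
compare_counts(c(10, 12, 11), c(20, 22, 21), method = "student_t")
#> Student's t (pooled variance): statistic = -12.25, p = 0.0002552
#>   (significant at p <= 0.05)
```

A full configured run (`run_pipeline("run.yaml", out_dir = "results/")`)
normalizes, pools, compares every population × level stratum, summarizes
counts and writes a provenance-stamped JSON report; a thin CLI over the same
functions lives in `inst/cli/cordmapper.R`.

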