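---
title: "Methods: normalized soma mapping and two-group distribution comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalized soma mapping and two-group distribution comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordmapper)
```

## The coordinate model

Soma positions digitized from transverse spinal-cord sections are measured
in polar form: a distance $D$ from the ventral-most midline point and an
angle $\alpha$ (degrees) between the horizontal medio-lateral axis through
that point and the ray to the soma. Each section carries its own frame —
height $H$ (ventral-most to dorsal-most point) and hemicord width $W$
(central canal to most lateral edge), both in one unit per dataset. The
normalized coordinates are

$$\mathrm{DV} = \frac{D\,\sin\alpha}{H}, \qquad
  \mathrm{ML} = \frac{|D\,\cos\alpha|}{W}.$$

Three conventions deserve comment because bench protocols rarely state
them:

* **Angle reference.** The sine must produce the vertical component, so
  $\alpha$ is defined from the horizontal axis, counter-clockwise for the
  right hemicord. Data digitized against the vertical axis can be read
  with `angle_from = "vertical"`, which maps $\alpha_h = 90 - \alpha_v$.
* **Side folding.** The absolute value in ML maps both hemisections onto
  one positive hemicord, so $\alpha$ and $180^\circ - \alpha$ are
  equivalent. Analyses that quantify one side of each section are
  unaffected; bilateral datasets fold coherently.
* **No clamping.** Measurement noise can push DV or ML slightly above 1.
  Values are kept as measured and flagged above 1.05 (`flag_threshold`),
  never clamped, so the statistics see the data as recorded. Flag counts
  surface in the pipeline report.

Because both coordinates are ratios, multiplying $D$, $H$, $W$ by any
common constant changes nothing: pixel- and micron-based datasets are
directly comparable, and the package never converts units (a dataset-level
unit declaration is validated for consistency but unused numerically).

## The two-sample test

Cells pooled across sections and embryos within one population ×
condition × axial level form samples $X$ ($n_1 \times 2$) and $Y$
($n_2 \times 2$). With pooled unbiased covariance
$S = ((n_1-1)S_1 + (n_2-1)S_2)/(n_1+n_2-2)$,

$$T^2 = \frac{n_1 n_2}{n_1+n_2}
        (\bar x - \bar y)^\top S^{-1} (\bar x - \bar y), \qquad
  F = \frac{n_1+n_2-p-1}{p\,(n_1+n_2-2)}\,T^2
  \;\sim\; F_{p,\;n_1+n_2-p-1}$$

under bivariate normality with common covariance. Assumptions and
safeguards:

* **Pooling caveat.** Treating pooled cells as independent observations
  mirrors the per-level pooled analyses this workflow reproduces, but it
  is pseudoreplication with respect to embryos. Every result records the
  contributing section and embryo counts and prints the caveat; the
  per-embryo alternative was deliberately not made the default because
  three embryos give the test almost no power and would not correspond to
  the published analyses this pipeline mirrors.
* **Permutation companion.** `hotelling_permutation_p()` permutes group
  labels over the pooled cells and uses the add-one estimator
  $p = (1 + \#\{T^2_{perm} \ge T^2_{obs}\})/(1 + n_{perm})$, which never
  returns 0 and is deterministic given its seed. It requires no
  distributional assumption and, in the suite's null simulations, agrees
  with the F approximation to well under 0.02 on average.
* **Degeneracy is an error.** If the pooled covariance is singular or has
  condition number above `1e12` (checked via its eigenvalues, which also
  enforces positive-definiteness), the test refuses to run rather than
  silently pseudo-inverting — constant coordinates and collinear samples
  are data problems the user must see.
* **Significance** is called at $p \le 0.05$ by default (`alpha`),
  inclusive at the boundary. Tests are reported per population and level
  without multiplicity correction, matching the per-comparison reporting
  convention of this analysis style; a Bonferroni pass across levels can
  be applied downstream since every p-value is in the report.

## Density estimation

1D profiles use a Gaussian kernel with Silverman's rule
$h = 1.06\,\hat\sigma\,n^{-1/5}$ as the `"auto"` bandwidth (passed
explicitly to `stats::density`, whose own default rule differs). The
evaluation grid spans $[\min(0, \min x - 3h),\; \max(1, \max x + 3h)]$: it
always covers the unit interval and extends three bandwidths past the
data, so the trapezoidal integral is 1 to within 1% without clipping at
the anatomical boundary. 2D maps use the product (diagonal-bandwidth)
kernel with the same per-axis rule; their grids are built identically, so
marginalizing a map over one axis reproduces the corresponding 1D profile
on the same grid (L1 distance well under 0.05 at 128 grid points). The
published density curves this emulates do not state their smoothing, so no
attempt is made to match their exact shapes — only the qualitative
smooth-curve presentation.

## Count and intensity statistics

Counts are summarized per group × level as mean ± SEM with the **embryo**
as replication unit: each embryo's sections are averaged first, then
SEM $= \mathrm{sd}/\sqrt{n_{embryos}}$. Section-unit mode exists for power
exploration and is labeled as such; a single-unit stratum reports SEM 0
and is flagged. Two-group comparisons use the pooled-variance Student's
*t* ("standard" *t*; Welch by flag) or the Mann–Whitney *U* (exact when
both $n \le 8$ and tie-free, normal approximation with tie correction
otherwise). The `auto` rule — Shapiro–Wilk non-significant at 0.05 in both
groups *and* variance-ratio F non-significant at 0.05, else Mann–Whitney —
is a stated convention, not a reconstruction of any published decision
rule, and is always overridable; the report names the test used. Under a
normal null its empirical size stays at or below 0.07 at nominal 0.05
(the pretest cascade trades a little size for robustness).

ISH intensity is the mean pixel value in a fixed-area rectangular signal
ROI (13,500 px² by default, ±one row/column of rounding) minus the mean of
an adjacent background ROI placed on unlabeled tissue; the subtraction
normalizes slide-to-slide background, and all values are arbitrary units.
ROIs are 0-based half-open `[row0,row1) × [col0,col1)` pixel rectangles
(the only place pixel-index semantics apply; coordinates are continuous);
overlap between signal and background ROIs is rejected. Condition
comparison is a pooled-variance *t* on per-embryo means of net intensity,
with fold change $\bar b/\bar a$ reported and flagged undefined when the
reference mean is ≤ 0.

## The synthetic generator

The generator exists so every stage can be validated by parameter
recovery without any imaging data. It emulates the study design it
accompanies: $n$ embryos × 5 sections per axial level, log-normal $H$ and
$W$ (positivity guaranteed; defaults around 200 px × 100 px with 8%
log-scale spread, typical of confocal section images), Poisson cell counts
per section (mean 40), per-population Gaussian-mixture positions truncated
to $[0, 1.05]^2$ by rejection (capped at 1,000 attempts per batch), marker
co-labeling by independent Bernoulli draws, and raw $(D, \alpha)$ emitted
by the exact inverse transform so normalization round-trips to $10^{-9}$.
The named presets (dI2: dorso-medial stream + ventral cluster; dI3: single
intermediate cluster; dI5: medial major + lateral minor; dI6:
ventro-medial) are stylized scenarios encoding qualitative anatomy —
editable YAML, not reconstructions of measured data.

Seeding is hierarchical: the master seed derives one stream per
(embryo, level, section) through a small congruential fold kept below
$2^{31}$, so adding sections or embryos never perturbs earlier draws and
identical `(truth, seed)` regenerate a dataset bit-identically.

What passing tests show — and what they do not: recovery and calibration
results demonstrate the estimator and tests behave correctly on data
satisfying their assumptions (mixture-normal positions, independent
cells). Real sections add digitization error, within-section spatial
correlation, embryo-level heterogeneity and boundary effects that the
generator only caricatures (truncation slightly distorts cluster weights
near edges, which the truth echo discloses); green tests therefore
validate the machinery, not any biological conclusion.

## Numerical and design choices

* Angles are accepted in degrees (bench tools report degrees) and
  converted once to radians.
* Per-section $H$ and $W$ are required; measuring once per embryo is not
  supported, since the per-section frame is what makes pooling across
  sections legitimate.
* Permutation ties are resolved toward significance with a relative
  $10^{-9}$ tolerance on $T^2_{perm} \ge T^2_{obs}$, so the identical-sample
  case yields exactly $p = 1$.
* Reports serialize with full double precision (`digits = NA`), making
  write→read an identity up to IEEE round-trip; the provenance block
  (config hash, seed, version) plus fixed seeds make reruns byte-identical
  apart from the timestamp line.
* Calibration sizes used by the suite and the acceptance script: 2,000
  replicates at $n = 30$/group for type-I error and power, 10,000
  permutations against the exhaustive 70-split enumeration, ~200 cells per
  group for shift recovery, 3 embryos × 5 sections for intensity recovery.
  These sizes put Monte-Carlo error well inside the tolerances being
  checked while keeping a full validation run in seconds.

## Known limitations

* No image segmentation or soma detection: coordinates and counts are
  inputs, produced by manual digitization upstream.
* No rostro-caudal coordinate: axial level is a categorical stratum.
* The pooled-cell test inherits the pseudoreplication caveat above;
  p-values on real data with few embryos are anti-conservative to an
  unknown degree.
* Mixture modeling lives only in the generator — the analysis side makes
  no attempt to count or fit clusters in real data.
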