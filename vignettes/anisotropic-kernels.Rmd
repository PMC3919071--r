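---
title: "Anisotropic kernels for peak-based meta-analysis: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anisotropic kernels for peak-based meta-analysis: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Peak-based meta-analysis recreates, for each study, a voxelwise effect-size
map from the handful of peak coordinates the study reports. The recreation
kernel is an un-normalised Gaussian: a voxel at distance $D$ mm from a peak
with effect size $d_{peak}$ receives

$$d_{voxel} = \exp\!\left(-\frac{D^2}{2\sigma^2}\right) d_{peak},
\qquad \sigma = \frac{\mathrm{FWHM}}{2\sqrt{2\ln 2}} \approx 0.425\,\mathrm{FWHM}.$$

The isotropic kernel takes $D$ to be Euclidean distance. This package
implements the anisotropic family: the distance between two *contiguous*
voxels with across-subject correlation $\rho$ is deformed to

$$D = \sqrt{(1-\alpha)\,D_{real}^2 + \alpha\, 2\sigma^2 \ln(1/\rho)},$$

where $\alpha \in [0,1]$ is the degree of anisotropy and $D_{real}$ the
Euclidean distance between voxel centers ($1$, $\sqrt2$ or $\sqrt3$ voxel
widths on the 26-neighborhood). The formula is the unique interpolation for
which, per step,
$\exp(-D^2/2\sigma^2) = \rho_{iso}^{\,1-\alpha}\,\rho^{\alpha}$ with
$\rho_{iso}=\exp(-D_{real}^2/2\sigma^2)$ the spatially constant correlation
implied by the isotropic kernel; the package asserts this identity over
randomized inputs. At $\alpha=1$ a perfectly correlated pair is at distance
0 and the kernel value along any path is the product of path correlations —
in particular it no longer depends on $\sigma$, which is why fully
anisotropic recreation is FWHM-invariant (asserted bit-near across FWHM 10,
20, 100).

Distances from a peak to non-contiguous voxels are shortest-path sums of
step distances over the 26-connected grid, computed by a compiled Dijkstra
with a binary heap. Propagation is **not** restricted to a tissue mask:
peaks outside the expected tissue still contribute, and recreated maxima can
be checked against reported coordinates. To prevent spurious "bridges"
through non-tissue, correlations at tissue probability $p$ below the
threshold $0.1$ are attenuated proportionally, $\rho \mapsto \rho\,p/0.1$
(divided by 2 at $p=0.05$, by 10 at $p=0.01$, continuous at the threshold).

Study-level maps convert reported t values to Cohen's $d$
($d = t\sqrt{1/n_1+1/n_2}$; one-sample $d = t/\sqrt{n_1}$), combine
overlapping peaks by a weighted average with the un-normalised kernel
factor $w_i = \exp(-D_i^2/2\sigma^2)$ as weight (so a voxel reached by a
single peak reproduces the kernel value exactly), attach the large-sample
variance $\mathrm{var}(d) = 1/n_1 + 1/n_2 + d^2/(2(n_1+n_2))$, and discard
voxels outside the tissue mask. Studies are pooled per voxel with a
DerSimonian–Laird random-effects model (method-of-moments $\tau^2$, weights
$1/(v_i+\tau^2)$), giving pooled effect, standard error and z maps.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `fwhm_mm` | mm | 20 | the conventional isotropic recreation width; irrelevant at $\alpha=1$ |
| `alpha` | — | 1 | fully anisotropic; the robust choice since results do not depend on FWHM |
| `tissue_threshold` | probability | 0.1 | attenuation threshold of the bridge guard |
| `cutoff_mm` | mm | = FWHM | beyond it the kernel value is below $d_{peak}/16$, negligible; comparison is strict (`>`) |
| `smoothing_sigma_mm` (template) | mm | 4 | matches the smoothing of the gray-matter segments the tissue average is built from ($\sigma$ = 4 mm, FWHM 9.4 mm) |
| `p_threshold`, `min_extent` (validation) | —, voxels | 0.001, 10 | the liberal cluster threshold of the validation design |

## The synthetic world

`simulate_validation_dataset()` builds the desk-scale stand-in for a
registered, segmented, smoothed multi-subject dataset:

- a $32^3$ grid at 2 mm with six spherical regions (radius 4 voxels, tissue
  level 0.9) in a zero-tissue background, boundaries softened by 2 mm
  smoothing;
- per subject, a density segment
  $\mathrm{clamp}\big(t(x)\,[\,S(1 + \ell z_{s,r} + \varepsilon) + \eta\,],\,0,1\big)$:
  baseline 1, one standard-normal latent factor $z_{s,r}$ per subject and
  region with weight $\ell = 0.6$, white noise $\varepsilon$ (SD 0.4)
  smoothed with the segment smoothing $S$ ($\sigma$ = 4 mm), a voxel-scale
  residual $\eta$ (SD 0.1), all scaled by the tissue map $t(x)$;
- 120 subjects, six balanced pairwise-orthogonal 60/60 splits (any two
  splits agree on exactly 60 subjects), and one injected group effect per
  split: split $j$'s group 1 gains $d \times$ (pooled within-region SD),
  $d = 1$, inside region $j$. Orthogonality makes each split blind to the
  other splits' effects except as variance.

Two generator decisions deserve emphasis. First, the baseline term: without
it the "segments" are zero-mean fields and their clipped average — the
tissue-probability map used for attenuation and masking — collapses to
nearly zero, emptying the analysis mask. Real segments are probability-scale
values whose subject mean approximates the tissue probability; the baseline
reproduces that. Second, the voxel-scale residual $\eta$: smoothing alone
leaves *any* two adjacent voxels almost perfectly correlated (neighbor
$\rho > 0.95$ even in pure-noise background), which no measured segment data
shows and which degenerates the anisotropic metric (every region collapses
to a point). With the residual, the phantom shows the structure the method
assumes — median within-region neighbor $\rho \approx 0.84$, background
$\rho \approx 0.17$ in the packaged world. The residual's SD (0.1) was
chosen to put within-region neighbor correlation near 0.9; it is a realism
parameter, not a fit to any validation outcome.

A consequence of injecting a spatially constant delta while subject SD
scales with tissue density is that t values peak near region *edges* (where
SD is smallest), not centers; extracted peak effect sizes are therefore
noticeably larger than the region-average effect, as with real cluster
maxima.

What a green validation run does and does not establish: it shows the full
pipeline — template, peaks, deformed-space recreation, scoring — behaves as
the theory predicts on a world with region-structured correlation
(reference identity at 100%, FWHM-invariance at $\alpha=1$, and a
substantial relative-MSE decrease under full anisotropy). It does not
reproduce any empirical MSE surface from real brain data: phantom regions
are geometric, noise is Gaussian and stationary, there is no registration
error, scanner effect or demographic structure, and the magnitude of the
improvement is dataset-specific.

## Numerical and design choices

- **Correlation type.** Pearson, across subjects, on the (smoothed) density
  values; series with zero variance (exact-zero background, out-of-grid
  neighbors) store a missing marker. Missing $\rho$ means an impassable
  edge when $\alpha > 0$.
- **$\alpha = 0$ ignores $\rho$ entirely** — including missing/negative
  values — so the isotropic limit is exactly the classical
  Euclidean-geodesic kernel rather than one with template-dependent holes.
- **Negative or zero $\rho$** (after attenuation) gives an infinite step;
  $\rho \ge 1 - 10^{-12}$ is treated as exactly 1 (zero-weight edges are
  legal). Distance updates within $10^{-12}$ are ties; tie-breaking cannot
  change distances.
- **Edge attenuation** uses the smaller tissue probability of the edge's
  two endpoints, keeping edge weights symmetric; the standalone
  `attenuate()` applies the voxelwise rule exactly as stated.
- **Cutoff** applies to the *deformed* total distance, strictly: voxels
  with $D$ exactly equal to the cutoff keep their value ($d_{peak}/16$ at
  the default).
- **Peak snapping**: world coordinate to nearest voxel through the inverse
  affine, halves rounded away from zero; the chosen voxel is recorded.
- **Wilcoxon signed-rank**: zeros dropped; exact two-sided p from the
  sign-flip distribution of the rank sum, computed by a small dynamic
  program over (doubled) midranks — valid with tied absolute differences
  and identical to the classical distribution without ties — for up to 25
  pairs, otherwise a tie-corrected normal approximation with continuity
  correction. With six paired values the smallest attainable exact
  two-sided p is $2/2^6 = 0.03125$; analyses that report, e.g., 0.030 for
  the same configuration use an asymptotic approximation. We default to
  the exact value and document the discrepancy rather than match it.
- **Orthogonal splits** come from columns of a Hadamard matrix on the
  smallest suitable divisor of $n$ (Sylvester doubling of base orders 1, 2,
  12, 20; rows repeated, subjects permuted by the seed), with a seeded
  randomized search as fallback. Two balanced splits can only be orthogonal
  when $n$ is a multiple of 4; infeasible requests are rejected with that
  explanation.
- **Scoring mask.** Relative MSE is computed over voxels with smoothed
  tissue probability $\ge 0.1$ (the attenuation threshold) where the truth
  map is defined; the "true" map is the unthresholded t-map converted
  voxelwise to $d$. One peak per cluster (the $|t|$ maximum, sign kept,
  first in array order on ties); both signs are emitted.
- **Random-effects estimator**: DerSimonian–Laird — closed-form,
  deterministic, the standard method-of-moments choice; only the
  intercept (mean effect) model is fitted. The effect-size variance is the
  textbook large-sample form. Both are stand-ins for the exact formulations
  of the original software, which are defined in prior work.
- **NIfTI-1 I/O** is implemented in the package (fixed 348-byte header,
  float32 output, sform affine; reader supports common datatypes, gzip,
  both endiannesses, scaling and the sform/qform/pixdim fallback chain)
  because the target environment ships no R NIfTI package. Round trips are
  cross-checked against an independent reader (nibabel) in the tests.

## Limitations

- Recreation weights for multi-peak combination (the un-normalised kernel
  factor) and the variance/GLM formulas are documented stand-ins for
  choices that the original method family leaves to cited prior work.
- The probability-of-union (ALE-style) combination is not implemented.
- No functional (fMRI/PET) correlation templates; the structural template
  is the intended general-purpose stand-in.
- No permutation thresholding, meta-regression or subgroup models.
- The synthetic phantom validates mechanics and direction-of-effect only;
  real-data MSE surfaces (and the optimal $(\alpha, \mathrm{FWHM})$) vary
  by dataset and must be estimated per meta-analysis when statistical maps
  are available.
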