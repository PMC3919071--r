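# anisokern

Anisotropic Gaussian kernels for coordinate-based meta-analysis of
neuroimaging studies.

## The problem

Most neuroimaging meta-analyses cannot pool full statistical maps — only the
*peaks* that papers report: MNI coordinates of cluster maxima with a t value
or effect size. Methods in the ES-SDM/ALE family therefore *recreate* a
brain-wide effect-size map per study by convolving a Gaussian kernel with
each peak, then combine studies voxelwise. The classical kernel is
isotropic: a voxel at distance `D` (mm) from a peak with effect size
`d_peak` receives

```
d_voxel = exp(-D^2 / (2 sigma^2)) * d_peak ,   sigma = FWHM / (2 sqrt(2 ln 2))
```

so every voxel 10 mm from the peak gets the same value — whether it lies in
the same anatomical region or across a sulcus in a different one.

`anisokern` implements the anisotropic alternative: inter-voxel distances
are *deformed* by the spatial correlation structure of the tissue, so that
voxels that co-vary across subjects are pulled closer together and
uncorrelated voxels are pushed apart. For two contiguous voxels with
across-subject correlation `rho`, real center distance `D_real`, and degree
of anisotropy `alpha` in [0, 1],

```
D = sqrt( (1 - alpha) * D_real^2  +  alpha * 2 sigma^2 * ln(1 / rho) )
```

(`alpha = 0` recovers the Euclidean step, `alpha = 1` is fully
correlation-driven). Distances from a peak to every other voxel are the
shortest-path sums of these steps over the 26-connected grid, computed with
Dijkstra's algorithm (compiled), cut off where the total exceeds the FWHM
(beyond which the kernel value is below `d_peak / 16`). Correlations in
voxels with tissue probability below 0.1 are attenuated proportionally
(divided by 2 at 0.05, by 10 at 0.01) to prevent "bridges" between separate
regions. At `alpha = 1` the recreated map is exactly independent of the
FWHM.

The package covers the full workflow:

- **templates** — per-voxel across-subject Pearson correlations with all 26
  neighbors (stored as 13 unique offset maps) plus a smoothed
  tissue-probability map, built from registered multi-subject volumes
  (`neighbor_correlations`, `save_template`/`load_template`);
- **kernel engine** — deformed-distance propagation and map recreation
  (`propagate`, `recreate_from_peak`, `combine_peak_maps`);
- **meta-analysis** — t-to-d conversion, effect-size variances, and a
  voxelwise DerSimonian–Laird random-effects model (`preprocess_study`,
  `random_effects_combine`);
- **validation harness** — orthogonal subject splits, two-sample t-maps,
  cluster-peak extraction (p = 0.001, extent >= 10), relative MSE over an
  (anisotropy x FWHM) grid against the "true" effect-size maps, and an
  exact Wilcoxon signed-rank comparison (`evaluate_grid`);
- **synthetic data** — a phantom generator emulating multi-subject
  tissue-density segments with region-structured correlations and injected
  group effects (`simulate_validation_dataset`), so everything is testable
  without any download;
- **I/O and CLI** — minimal NIfTI-1 read/write (no external NIfTI package
  required), TSV peak tables, and an `ak_cli()` umbrella command
  (`simulate`, `build-template`, `recreate`, `meta`, `validate`).

## Worked example

Simulate the packaged validation world (a 32^3, 2 mm phantom with six
spherical regions; 120 subjects with region-level latent factors; six
orthogonal 60/60 splits, each with one injected regional effect of d = 1),
build a correlation template from the subjects, and score recreation
accuracy:

```r
library(anisokern)

ds  <- simulate_validation_dataset(n_subjects = 120, k = 6, d = 1.0, seed = 17)
tpl <- neighbor_correlations(ds$volumes)
tpl
#> <correlation_template> 32x32x32 voxels, 13 offset maps
#>    tissue=unknown, n_subjects=120, smoothing_sigma_mm=4

# one split: t-map, peak extraction, single-peak recreation
g   <- ds$splits$assignments[1, ]
tm  <- two_sample_t_map(ds$volumes[g == 0], ds$volumes[g == 1])
pks <- extract_peaks(tm$t, tm$df)           # p = 0.001, extent >= 10
length(pks)                                  # 1 cluster peak, t = -13.55
dpk <- peak(pks[[1]]$coord_mm, t_to_d(pks[[1]]$value, 60, 60), "d")
rec <- recreate_from_peak(tpl, dpk, kernel_config(fwhm_mm = 20, alpha = 1))
rec
#> <volume_grid> 32x32x32 voxels, 2x2x2 mm
#>   values in [-2.473, -0], 0 NA

# relative-MSE surface over (alpha, FWHM), reference = isotropic 20 mm
grid <- evaluate_grid(ds$volumes, tpl, alphas = c(0, 1),
                      fwhms = c(10, 20, 100), split_plan = ds$splits)
grid
#> <validation_grid> relative MSE (%), mean over 6 splits
#>      fwhm
#> alpha   10    20    100
#>     0 54.4 100.0 1482.4
#>     1 36.9  36.9   36.9
#> peaks per split: 1, 1, 1, 1, 1, 1
```

Reading the surface: the reference cell (alpha = 0, FWHM = 20) is 100% by
construction. On this phantom, narrowing the isotropic kernel helps (54%)
and widening it is disastrous (1482%), while full anisotropy reaches 37% *at
every FWHM* — the recreated maps at alpha = 1 are identical for FWHM 10, 20
and 100, so no kernel-width choice is needed. The per-cell signed-rank
p-values against the reference are 0.031 (the exact two-sided minimum
attainable with six splits).

## Command line

```sh
anisokern() { Rscript "$(Rscript -e 'cat(system.file("cli","anisokern",package="anisokern"))')" "$@"; }
anisokern simulate --out data/ --n-subjects 120 --splits 6 --seed 1
anisokern build-template --subjects data/ --tissue gray --out tpl
anisokern recreate --template tpl --peaks peaks.tsv --fwhm 20 --alpha 1 --out rec.nii.gz
anisokern meta     --template tpl --peaks peaks.tsv --alpha 1 --out meta
anisokern validate --subjects data/ --template tpl --alphas 0,0.5,1 --fwhms 10,20,100 --out val
```

Peak tables are TSV with header `study_id x y z value stat n1 n2`
(`stat` is `t` or `d`; `n2 = 0` marks one-sample designs); volumes are
NIfTI-1 (`.nii` / `.nii.gz`), world coordinates MNI mm.

See `vignettes/anisotropic-kernels.Rmd` for the model, parameter and design
discussion.
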