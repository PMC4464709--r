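# atriarecon

Non-model-based left-atrial (LA) volumetry from a handful of arbitrarily
oriented 2D cine MR slice contours.

A single-breath-hold cine acquisition can cover the left atrium with just
two long-axis and three short-axis slices. `atriarecon` reconstructs a
closed 3D chamber surface — and hence its volume, per cardiac phase — from
those few closed contours, without assuming a chamber shape: each plane's
contour defines an inside/outside indicator (+1 inside, −1 outside, the
contour its zero set), the indicator is interpolated into space, and the
zero level set is extracted as a watertight triangle mesh whose enclosed
volume

V = |Σ_faces det(a, b, c)| / 6

is the measurement. The package also provides:

* the model-based comparator, the modified bi-plane area-length formula
  `V = 0.848 · A_4ch · A_2ch / ((L_4ch + L_2ch)/2)`;
* LA time-volume curves and functional indices (maximal / minimal /
  pre-contraction volume, total/passive/active emptying volumes and
  fractions, mean filling and contraction rates, "passive LA flow");
* synthetic LA phantoms (oval large/small, oblique, spherical, curved)
  with analytic reference volumes, sliced by configurable orientation
  strategies, static or animated along a prescribed volume curve;
* Bland-Altman agreement statistics (limits at ±2 SD, percent differences
  on the pairwise mean), paired t-tests, the 2×2 repeated-measures ANOVA
  for the orientation-by-method interaction, and an endocardial border
  sharpness metric (mean reciprocal 20–80% edge width over 8 radial
  profiles).

Inputs are contour-exchange JSON files (plane geometry in DICOM
patient-coordinate convention plus per-plane, per-frame contours) or
binary segmentation masks in NIfTI; see `read_contours()` and
`read_mask_nifti()`.

## Worked example

```r
library(atriarecon)

# a 55 ml spherical phantom, sliced with the aligned strategy
ph <- make_phantom("sphere", 55)
ds <- generate_strategy(ph, strategy = 1)

rec <- reconstruct_frame(ds, config = recon_config(grid_mm = 1))
rec
#> <la_reconstruction> frame 0: 55.13 ml (62952 faces, grid 1 mm, signed_distance)

area_length_volume(ds)$volume_ml
#> [1] 54.88

# a cine phantom with a prescribed cycle, reconstructed frame by frame
cds <- generate_cine_phantom(ph, v_max = 82.6, v_min = 43.6, v_pre_a = 64.4,
                             n_frames = 34)
curve <- reconstruct_cine(cds, config = recon_config(grid_mm = 1.5))
idx <- la_indices(curve, lv_sv = 104)
glance(idx)
#> # A tibble: 1 × 8
#>   v_max v_min v_pre_a total_emptying total_ef passive_fraction active_fraction passive_la_flow
#>   <dbl> <dbl>   <dbl>          <dbl>    <dbl>            <dbl>           <dbl>           <dbl>
#> 1  82.7  43.6    64.5           39.1     47.3             46.7            53.3            64.9
```

The reconstruction recovers the 55 ml sphere to within 0.3%, the
area-length comparator lands at `0.848/(8/3π)` ≈ 0.999 of the truth for
model-conforming shapes, and the cine pipeline returns the prescribed
landmark volumes (82.6 / 43.6 / 64.4 ml) within a few tenths of a percent,
so the derived emptying fractions match their prescribed values.

The full orientation study — five phantom shapes, three slice-orientation
strategies, both reconstruction methods, Bland-Altman summaries and the
alignment-by-method ANOVA — runs with:

```r
run_validation_suite(validation_config(grid_mm = 1, seed = 1, out_dir = "results"))
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/atriarecon` (subcommands `phantom`, `reconstruct`, `area-length`,
`indices`, `agreement`, `validate`).

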