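# threshsurf

Quantifies how the single grey-intensity threshold used to segment bone
from 3D radiographic volumes (CT and cone-beam CT) affects the resulting
surface models — the models that orthodontics and craniofacial research
superimpose on the anterior cranial base to measure growth and treatment
change.

## What it computes

For a volume with a voxel labelling of the structure of interest:

1. **Reference threshold** — the mean intensity of the *interface voxels*
   (voxels of either class with ≥ 1 neighbour in the opposite class);
   partial-volume averaging places this mean at the bone boundary. On the
   0–1000 rescaled intensity range of a two-material structure with
   levels `I_soft` and `I_bone`, the estimator recovers
   `(I_soft + I_bone) / 2`.
2. **Threshold family** — reference + {−60, −40, −20, 0, +20, +40, +60},
   and a surface model (topology-consistent marching-tetrahedra
   isosurface) at each value, cropped to a region of interest.
3. **Effect metrics** per offset model against the reference model:
   directed mean absolute distance `MAD = mean_i dist(p_i, S_ref)`
   (exact point-to-surface, BVH-accelerated) before superimposition; the
   rigid best-fit movement from point-to-plane ICP
   (`argmin sum(((R p + t − q) · n_q)^2)`, 50 iterations, exact
   correspondences) decomposed into tx/ty/tz (mm) and rx/ry/rz (degrees);
   and MAD after superimposition.
4. **Statistics** — permutational MANCOVA on Euclidean distances with
   residual permutation under the reduced model (999 permutations),
   plus Friedman / Wilcoxon signed-rank pairwise tests with Bonferroni
   correction.

A seeded synthetic phantom generator (two-material cranial-shell
geometry, Gaussian partial-volume blur, additive noise, smooth
multiplicative CBCT-like bias field) provides analytic ground truth, so
the entire pipeline is validated without patient data.

## Worked example

```r
library(threshsurf)

# ten seeded phantoms per acquisition mode, full sweep on each
records <- phantom_study(n_per_mode = 10, seed = 1)
summarize_sweep(records)
#> # A tibble: 36 × 7
#>   mode     threshold_offset status     n mad_median mad_min mad_max
#>   <chr>               <dbl> <chr>  <int>      <dbl>   <dbl>   <dbl>
#> 1 cbct_low              -60 after     10     0.0751  0.0663  0.0807
#> 2 cbct_low              -60 before    10     0.171   0.158   0.179
#> 3 cbct_low              -40 after     10     0.0482  0.0425  0.0534
#> 4 cbct_low              -40 before    10     0.110   0.102   0.116
#> 5 cbct_low              -20 after     10     0.0235  0.0212  0.0250
#> 6 cbct_low              -20 before    10     0.0535  0.0500  0.0553
#> # ...

plot_mad(records)       # MAD box plots by offset, mode and status
plot_movement(records)  # movement-component box plots

records$patient <- as.integer(factor(records$volume_id))
tidy(perm_mancova(records, mad_mm ~ patient + mode * factor(threshold_offset),
                  n_permutations = 999, seed = 1))
#> # A tibble: 4 × 5
#>   term                             df    sum_sq pseudo_F p_perm
#>   <chr>                         <int>     <dbl>    <dbl>  <dbl>
#> 1 patient                           1 0.0000869   0.0225  0.89
#> 2 mode                              2 0.0872     11.3     0.001
#> 3 factor(threshold_offset)          5 0.124       6.41    0.001
#> 4 mode:factor(threshold_offset)    10 0.0357      0.925   0.514
```

The acquisition mode and the threshold offset both drive the MAD
strongly (p at the permutation floor of 0.001); the phantom "patient"
covariate carries nothing, as it should for independently seeded
phantoms.

Reading the records: `mad_mm` on `status == "before"` rows is the
distance between the offset model and the reference model in their
original positions — it grows monotonically with |offset| (about
0.05 mm at ±20 up to 0.17 mm at ±60 for the CBCT presets, roughly twice
that for the CT preset, whose coarser voxels give a wider partial-volume
edge). The `after` rows show what remains once the best-fit rigid motion
is removed: for the CT-like phantoms ICP recovers most of the effect
(median gap ≈ 0.16 mm), for the CBCT-like phantoms (bias field on) less
is rigidly recoverable. `tz` and `rx` — vertical translation and
anteroposterior rotation — dominate the movement components, as expected
for a bowl-shaped structure whose surface shifts along its normals when
the threshold moves.

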