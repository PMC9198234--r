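# femurfe

Segmentation sensitivity analysis for finite element (FE) models of the
femoral head.

## The problem

FE analysis of bone inherits everything from the segmentation that precedes
it: a voxel-level decision about what counts as osteological structure. Two
segmentations of the same CT volume can be visually indistinguishable yet
differ enough to change the biomechanical quantities computed from the
resulting models. `femurfe` is an end-to-end, fully synthetic testbed for
quantifying that effect, aimed at researchers who build FE models from
medical images and want to know how much their conclusions depend on the
segmentation step.

The pipeline: generate femoral-head CT phantoms with known ground truth →
segment each phantom with Kittler–Illingworth (KI) minimum-error
thresholding and three narrowed variants → crop at the head–neck junction
and orient along +Z → convert voxels to tetrahedral FE models → solve a
standardized linear-elastic compression → compare four whole-model measures
across segmentation groups.

## The methods at its core

**KI thresholding.** The intensity histogram is modeled as two Gaussians
split at candidate threshold *t*; the threshold minimizes the
minimum-error criterion

    J(t) = 1 + 2 [P1 ln s1 + P2 ln s2] - 2 [P1 ln P1 + P2 ln P2]

with class weights P and standard deviations s on each side of *t*. The
variants KI-99.0, KI-97.5 and KI-95.0 keep the central 99.0%, 97.5% and
95.0% of the KI-derived bone intensity range `[t, max I]` — controlled
segmentation variations of 1.0%, 2.5% and 5.0%.

**FE model.** Constant-strain tetrahedra (six per voxel), isotropic
elasticity with E = 16800 MPa and Poisson ratio 0.3, 1800 N compressive load
distributed over the proximal head surface, inferior (cut) surface fully
fixed. Per specimen the package reports mean displacement magnitude (mm),
mean compression-positive pressure (MPa), mean von Mises stress (MPa) and
mean effective Lagrange strain, and compares each narrowed variant against
KI per side with two-sample t tests (Welch by default).

## Worked example

```r
library(femurfe)

ph <- generate_phantom(phantom_params(seed = 1L))
ph$volume
#> <ct_volume> phantom (left)  32 x 32 x 32 voxels, spacing 1 x 1 x 1 mm
#>   intensity range [-88.2, 1331.5]

segment_volume(ph$volume, "KI-95.0")
#> <binary_mask> 32 x 32 x 32 voxels, 3443 foreground (10.5%)
#>   method KI-95.0, range [258.20, 1303.99]

r <- analyze_specimen(ph$volume, ph$truth, "KI-95.0", pipeline_config())
r$tet
#> <tet_mesh> 3842 nodes, 18168 tets, volume 3028.000 mm^3
#>   node sets: inferior_fixed (101), proximal_load (312)
r$summary
#>   specimen_id side  method mean_displacement mean_pressure mean_stress mean_strain
#> 1     phantom left KI-95.0          0.006978         3.148       9.572   0.0004937
```

The mask keeps voxels in the narrowed range [258.2, 1304.0]; the cropped
head becomes an 18k-element model; under 1800 N the model averages 9.57 MPa
von Mises stress and 3.15 MPa pressure, with a mean displacement of 7 µm at
this reduced phantom scale. Re-running with method `"KI"` gives a slightly
larger mask and correspondingly lower stress — the effect the package
exists to measure.

A full cohort comparison:

```r
run <- run_pipeline(pipeline_config(n_left = 20, n_right = 20, base_seed = 1))
run$tables$means        # per-side, per-method group means of the 4 measures
generics::tidy(run$tables)  # 12 comparisons per side: t, df, p, significance
ggplot2::autoplot(run$tables)  # group-mean trends across methods
```

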