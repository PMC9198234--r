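---
title: "How segmentation variation propagates into femoral-head finite element models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How segmentation variation propagates into femoral-head finite element models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Finite element (FE) analysis of bone starts from a segmentation: a binary
decision, voxel by voxel, about what counts as osteological structure. Two
segmentations of the same CT scan that look indistinguishable on screen can
still differ in thousands of voxels, and those differences change the
geometry — and therefore the mechanics — of every model built downstream.
`femurfe` provides a fully synthetic, end-to-end testbed for quantifying this
effect: it generates femoral-head CT phantoms with known ground truth,
segments them with a family of threshold-based methods that differ by a
controlled amount, builds tetrahedral FE models of the cropped femoral head,
solves a standardized compressive load case, and compares four whole-model
biomechanical summaries across the segmentation variants.

## The segmentation family

The reference method is Kittler–Illingworth (KI) minimum-error thresholding.
The intensity histogram is modeled as a mixture of two Gaussians split at a
candidate threshold $t$; the threshold minimizes

$$J(t) = 1 + 2\,[P_1 \ln \sigma_1 + P_2 \ln \sigma_2]
       - 2\,[P_1 \ln P_1 + P_2 \ln P_2],$$

where $P_k$ and $\sigma_k$ are the weight and standard deviation of the
sub-histogram on each side of $t$. The implementation evaluates $J$ at every
bin boundary by cumulative moments; ties are broken towards the lower
threshold so results are deterministic, and zero within-class variances (spike
histograms) are floored at the single-bin variance $w^2/12$ for bin width
$w$. The same criterion evaluated by an independent brute-force scan is the
oracle in the test suite.

The full KI method keeps every voxel in $[t, \max I]$. The narrowed variants
KI-99.0, KI-97.5 and KI-95.0 keep only the central $p$ = 99.0%, 97.5% and
95.0% of that intensity interval, trimming both ends symmetrically by
$(1-p)/2$ of the width — intensity-range variations of 1.0%, 2.5% and 5.0%.
Trimming both tails is the reading most consistent with the variants' known
behavior (excluding residual soft tissue at the low end *and* bright imaging
artifacts at the high end); since "the central p% of the intensity values"
could also be read as a statement about the voxel-intensity *distribution*,
that alternative is implemented as `segment_volume(mode = "percentile")`, but
the range reading is the default and is what the package's results use.
Narrowed ranges are nested by construction, so the masks are nested too —
a property the tests assert on every input. After thresholding, only the
largest 26-connected component is kept, the voxel-space analog of
isolated-piece removal.

## The phantom and what it does (and does not) emulate

Each specimen is a sphere-plus-cylinder femoral head and neck: a cortical
shell (default thickness 2 mm) of high intensity (1200) around a trabecular
interior (700), embedded in soft-tissue background (80), with additive
Gaussian noise (SD 40). The trabecular compartment additionally carries a
smooth random texture with standard deviation `texture_factor * noise_sd`
(default $4 \times 40 = 160$), emulating the broad intensity continuum of
real trabecular bone (marrow spaces, partial-volume averaging). Tying the
texture to the noise level means a noiseless phantom collapses to exactly
three intensity plateaus, which the oracle tests exploit: below any threshold
between background and trabecular intensity, segmentation must recover the
ground-truth mask exactly.

The default geometry (head radius 9 mm on a $32^3$ grid of 1 mm voxels) is a
reduced-scale femoral head, roughly 40% of adult linear scale. The choice is
a deliberate trade-off: it keeps a full two-sided cohort (66 + 63 specimens,
four methods each — 516 FE models) computable on a single desktop core in
minutes while preserving all the structure the analysis needs (bimodal
histogram, cortical shell several voxels thick, hundreds of thousands of
degrees of freedom across a cohort). The test suite and the acceptance
script additionally use an even smaller $24^3$ "toy" configuration for the
cohort-count check, and all sizes are parameters of `phantom_params()`.

Artifacts are modeled as small bright ellipsoids placed outside the bone.
They give the high-tail trim of KI-95.0 something real to exclude and the
largest-component cleanup something to remove; tests assert that KI-95.0
never retains more artifact voxels than KI.

What the phantom does *not* emulate: realistic CT physics (beam hardening,
partial-volume blur at interfaces, anisotropic voxels), anatomically
realistic whole-femur geometry, or cortical thickness variation. Passing
tests therefore demonstrate the pipeline's internal correctness and the
direction of the segmentation-sensitivity effect under controlled conditions,
not quantitative agreement with any particular cadaveric dataset.

Cohort variation multiplies radii/cortical thickness and the two bone
intensities by per-specimen Gaussian factors (relative SD 5% and 2%,
clamped at 2.5 SD so generator invariants always hold). Specimen $i$ uses
seed `base_seed + i - 1`, so cohorts are reproducible and extendable.

## Meshing and standardization

Surfaces are extracted by marching tetrahedra on the same six-tetrahedra cube
decomposition used for solid meshing; the indicator field is pre-smoothed
with a 1-voxel Gaussian so the isosurface tracks the smooth anatomy rather
than the voxel staircase (a sphere's area is recovered to well under 5%),
with an automatic fallback to the raw indicator when smoothing would erase a
tiny object. Surface standardization removes duplicate faces, keeps the
largest connected component, closes boundary loops by centroid fans, and
applies shrink-free Taubin smoothing ($\lambda = 0.5$, $\mu = -0.53$, 10
passes) — a deliberately local, deterministic alternative to global surface
reconstruction, which would rebuild the surface rather than standardize it.
The smoothing affects exported surfaces only: the FE mesh is built directly
from voxels, so surface processing never changes the mechanics.

The head is cropped at the analytic head–neck junction plane carried by the
ground truth (for real volumes the plane is a required user input, since no
landmark detector is included), rotated so the plane normal aligns with +Z,
and resampled at the original spacing by nearest-neighbor lookup; in the
output frame the plane sits at $z = 0$.

Solid meshing splits every retained voxel into six tetrahedra sharing the
cube's main diagonal: deterministic, face-compatible across neighbors,
strictly positive volumes, and total volume exactly equal to the voxel
volume. Only the largest *face-connected* (6-connected) component is meshed:
voxels attached by an edge or corner alone would hinge freely under
face-sharing tetrahedra and make the stiffness singular. Two selections are
attached: `inferior_fixed` (all nodes on the minimal-z layer, i.e. the cut
surface) and `proximal_load` (boundary faces whose outward normal lies
within 45° of +Z and whose centroid is in the top 20% of the z-extent; both
the cone and the fraction are configurable, since "the proximal aspect" is a
qualitative description).

## The FE model

Standard 4-node constant-strain tetrahedra with isotropic linear elasticity
(default E = 16800 MPa, Poisson 0.3), assembled sparsely and solved by
supernodal sparse Cholesky; the solve verifies a relative residual below
1e-8 and that reactions balance the applied load. Sparse direct
factorization handles every problem size this package produces (cohort
models run at $10^4$–$10^5$ degrees of freedom), so no iterative fallback is
provided. Nodally-integrated tetrahedra, which trade implementation
complexity for less locking, are out of scope; constant-strain elements are
the verified baseline, and the verification battery (exact patch test, exact
uniform uniaxial state, monotone convergence, rotation equivariance) pins
their behavior.

The load case distributes the total force (default 1800 N, the standing
joint reaction of one leg) over the proximal load faces proportionally to
face area, split equally among face nodes, then rescales so the force sum is
exact to machine precision. The inferior surface is fully fixed.

Per element, with displacement gradient $H$: small strain
$\varepsilon = (H + H^\top)/2$, stress $\sigma = \lambda\,\mathrm{tr}
(\varepsilon) I + 2\mu\varepsilon$, von Mises stress $\sqrt{3/2\, s\!:\!s}$,
pressure $-\mathrm{tr}(\sigma)/3$ (compression-positive, so compressive
loads give positive pressures), Green–Lagrange strain
$E = (H + H^\top + H^\top H)/2$, and as the single reported strain scalar
the effective (von-Mises-equivalent) invariant $\sqrt{2/3\, e\!:\!e}$ of its
deviator $e$. A strain is a small dimensionless number whose magnitude under
these loads lands near $10^{-3}$; reporting the effective invariant rather
than the trace is a convention choice, and the first invariant is available
from the stored tensors. The four specimen summaries are the mean nodal
displacement magnitude and unweighted element means of pressure, von Mises
stress and effective strain — whole-model averages, chosen so local extrema
cannot dominate group comparisons; volume-weighted means are available via
`summarize_specimen(weighted = TRUE)`.

## Group statistics

Left and right cohorts are never pooled. For each side, each narrowed
variant is compared against full KI for each of the four measures — 12
comparisons per side. The default test is Welch's two-sample t, two-sided,
$\alpha = 0.05$, with no multiple-testing correction (per-comparison
reporting); both choices are configurable (`mode = "paired"` exploits that
the groups contain the same specimens, `p_adjust = "holm"` corrects). The
degenerate all-identical case returns $t = 0, p = 1$ rather than an error.
`null_rejection_rate()` checks calibration: with both groups drawn from one
distribution, the rejection rate at $\alpha$ must estimate $\alpha$.

## Numerical choices and degenerate inputs

* Histogram: 256 bins over the full range by default; KI is
  resolution-dependent and the bin count is exposed.
* Threshold ties: lowest minimizer; spike histograms: variance floor
  $w^2/12$.
* Zero-width intensity ranges pass through narrowing unchanged.
* Constant volumes are flagged degenerate and refuse thresholding with a
  typed error; empty masks, empty cropped regions, empty load/fixed sets and
  floating meshes all raise typed errors naming the stage.
* Isosurface level 0.5 with 1-voxel Gaussian pre-smoothing; single-voxel
  objects fall back to the raw indicator (closed octahedron, Euler
  characteristic 2).
* Solver residual tolerance 1e-8 relative; solutions are rejected, not
  repaired, when it is exceeded.

## What a cohort run shows

On default cohorts the group means of all four measures increase from KI to
KI-95.0: narrowing the intensity range removes dim trabecular voxels
(interior porosity) and the brightest cortical voxels (shell pitting), so
the same 1800 N load acts on less bone. The displacement measure responds
most weakly and can show sub-0.1% non-monotone steps at small cohort sizes:
each model's node set changes with the mask, so the mean-over-nodes measure
carries discretization noise that the element-mean measures largely avoid.
The statistical layer sees the same ordering through the per-side t tests,
with significance appearing first for the 5% variation — the same
qualitative pattern that motivates standardizing segmentation before any FE
study.

Problem sizes used by the shipped checks: the cohort-count run uses $24^3$
toy phantoms (about 6000 tetrahedra per model, 516 models); the trend check
uses the $32^3$ default at 20 specimens per side over three seeds; FE
verification uses cubes up to $8^3$ voxels (3072 tetrahedra). These sizes
are the package's chosen desk-scale defaults; every one of them scales up by
changing `phantom_params()`.

## Known limitations

* The phantom's junction plane is analytic; real data need a user-supplied
  cropping plane.
* Constant-strain tetrahedra are stiff in bending at coarse resolution;
  absolute displacement magnitudes at $24^3$–$32^3$ should be read as
  model-scale quantities, not patient-scale predictions.
* The segmentation family is threshold-based by design; the package is a
  sensitivity testbed, not a segmentation benchmark.
* Left/right sides differ only by label and cohort seed, not by mirrored
  anatomy.
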