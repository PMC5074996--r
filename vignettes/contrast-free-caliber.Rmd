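---
title: "Contrast-free vessel caliber from multi-scale vesselness: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrast-free vessel caliber from multi-scale vesselness: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quantifying pulmonary vessel calibers from micro-CT normally requires an
iodinated contrast agent: vessels are only a little denser than blood-filled
soft tissue, and in 2D projections everything overlaps. In the lung,
however, vessels sit against air-filled parenchyma, so in a reconstructed
3D volume they are bright tubes on a dark background. This package exploits
that geometry: instead of measuring intensity edges, it measures the *size
of the Gaussian kernel* at which a tubularity filter responds most
strongly, and converts that scale to a physical diameter through a
calibration fitted on synthetic tubes of known size.

## Vesselness and the S_MAX volume

For a volume $I$ and a Gaussian kernel scale $S$ (voxels), we smooth with
an isotropic Gaussian of standard deviation $S$ and form the Hessian by
central differences, multiplying each second derivative by $S^\gamma$
(default $\gamma = 2$) so magnitudes are comparable across scales. With
eigenvalues ordered $|\lambda_1| \le |\lambda_2| \le |\lambda_3|$, the
Frangi vesselness is

$$V_S = \Big(1 - e^{-R_A^2/2\alpha^2}\Big)\, e^{-R_B^2/2\beta^2}\,
        \Big(1 - e^{-\|\lambda\|^2/2c^2}\Big),$$

with $R_A = |\lambda_2|/|\lambda_3|$ separating tubes from plates,
$R_B = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$ suppressing blobs, and
$\|\lambda\\|^2 = \sum_i \lambda_i^2$ the structureness. For bright tubes
$V_S = 0$ wherever $\lambda_2 > 0$ or $\lambda_3 > 0$, and at degenerate
denominators ($\lambda_2\lambda_3 = 0$) we define $V_S = 0$ — there is no
structure to enhance, and no NaN may escape.

`multiscale_vesselness()` takes the pointwise maximum of $V_S$ over the
scale list (default integer scales 1–30) as the *probability volume* and
records the argmax scale as *S_MAX*. Ties take the smallest scale, a
deterministic choice that biases toward finer structure; voxels with zero
probability carry `NA`. The filter streams one scale at a time, so the
peak working set is a fixed number of volume-sized grids regardless of how
many scales are requested.

### Parameter defaults

* `alpha = 0.5`, `beta = 0.5` — the standard sensitivity choices for this
  filter family; both exposed.
* `gamma = 2` — second-derivative scale normalization, required for the
  cross-scale argmax to be meaningful.
* `scales = 1:30` (voxels) — integer steps; the step is exposed. The
  scale quantization is visible in D_CT: one scale step corresponds to
  roughly 3 px of diameter through the calibration slope.
* `c = "auto"` — **half of the maximum Hessian Frobenius norm over the
  volume across all scales of the run.** This global normalization is a
  deliberate design decision. If instead $c$ is re-derived per scale, the
  structure that attains the per-scale maximum has its structureness term
  pinned near its ceiling at *every* scale; its vesselness curve goes flat
  and the argmax drifts to the top of the scale range, destroying the
  S_MAX–diameter relation for the largest vessel in the volume (and for
  any single-structure image). With one global $c$ the structureness term
  decays away from a structure's natural scale and the argmax sits where
  the scale-normalized response genuinely peaks. Auto-$c$ scales linearly
  with the input, so the argmax is invariant to multiplying the volume by
  a positive constant. A fixed numeric $c$ skips the extra pass over
  scales that auto mode needs.
* `polarity` — `bright-tubes` by default (water-dense vessels against
  air); `dark-tubes` negates the volume first.

Voxels closer to the volume border than $3\,S_{MAX}$ are flagged in a
validity mask: the filter support is truncated there (reflective
boundaries) and the response is not trustworthy.

## From S_MAX to millimetres

On synthetic long tubes the argmax scale grows linearly with tube
diameter. The calibration phantom (`default_calibration_phantom()`)
contains ten parallel tubes with diameters geometrically spaced from
3.14 px to 62.8 px, all rotated by (x = 30°, y = 15°, z = 0°) so they are
oblique to the grid. Only the diameter range and rotation are fixed by
the study design; tube count, spacing and edge handling are this
package's choices: ten tubes (dense at small scales), a
surface-to-surface clearance of at least one largest-diameter
(so neighbours are invisible to the filter and to the line profiles), and
supersampled (3×) partial-volume edges, which is what real CT exhibits
and what an FWHM measure assumes. Tubes run along the canonical x axis
before rotation and centers spread along the image-vertical direction, so
the frontal projection shows ten disjoint strips.

The calibration measures, per tube and per replicate line position
(25 positions by default, spread over the central 55% of each strip):

* **D_PROJ** — FWHM diameter on the maximum-intensity projection. The
  silhouette of a cylinder under parallel projection has width equal to
  its true diameter at any view angle, so D_PROJ is an unbiased caliber
  reference.
* **S_MAX** — the maximum value along the same line on the projected
  centerline S_MAX image (the skeleton of the flood-fill segmentation,
  with S_MAX mapped to its nodes and forward projected in the same
  geometry).

An ordinary least-squares fit of S_MAX on D_PROJ gives the calibration
model. `smax_to_diameter()` is its exact algebraic inverse:
$D_{CT} = (S_{MAX} - b)/m \cdot \text{voxel size}$, with values at or
below the intercept flagged non-physical. The intercept is fitted freely
(a force-through-origin option exists); whether the original analysis
kept the intercept is not stated, and a free intercept also absorbs part
of the scale quantization.

## FWHM protocol

`fwhm_diameter()` implements the five-parallel-line protocol: the central
line plus four copies offset perpendicularly by 1 px (the spacing is
exposed; the source describes "five measurements parallel to this line"
without the spacing). Each profile is sampled by bilinear interpolation
at ≤ 0.25 px steps. The baseline is the lower of the two outer-10% tail
means — robust when one end of a line lands near another vessel. The
width is the distance between the two half-level crossings nearest the
peak, each localized by linear interpolation; sub-pixel localization
matters because calibers down to ~3 px are measured. Profiles without two
crossings are dropped and counted; the diameter is the mean of the valid
widths.

## Segmentation and centerline

Flood-fill segmentation grows 26-connected regions from seeds inside
`{probability >= threshold}`. The threshold default (0.05) reflects how
sparse and high-contrast the vesselness output is; it is configuration,
not physics. Skeletonization is sequential topology-preserving thinning
(six directional subiterations per pass; a voxel is deleted only when it
is a simple point — one 26-component of foreground in its neighbourhood,
one adjacent 6-component of background — and not a curve endpoint). The
contract is *any* unit-width 26-connected, topology-preserving skeleton;
the tests check the contract (axis accuracy, idempotence, component and
branch counts), not an algorithm identity. Remaining cycles are broken by
a maximum-probability spanning forest, i.e. the lowest-probability edge in
each cycle is dropped. Terminal spurs shorter than 3 nodes are pruned by
default (a switch exposes this). Branch generations are counted from a
root chosen as the endpoint with the largest mapped S_MAX — the proximal
end of a vascular tree is its thickest vessel; the root is overridable.

## Projection

Projection is parallel-beam and orthographic: rotation about the vertical
axis followed by a per-ray maximum (exact column maximum at 0°). The real
instrument is cone-beam; we absorb magnification into the effective voxel
size (detector pitch × source-to-isocenter / source-to-detector, 21.9 μm
for the geometry shipped in the protocol module) and accept the residual
divergence as a documented limitation — the calibration and comparison
operate on relative in-plane calibers. Tree attributes are projected by
nearest-pixel splatting with max-combine; an optional 3×3 dilation exists
for display only.

## What the synthetic data does and does not emulate

The phantoms provide exact ground truth: analytic cylinders (with
partial-volume edges), a reproducible branching tree of capsule segments
(two children per node, diameter ratio per generation, segment length
1.9 diameters — a plausible vascular L/D that also keeps the default
three-generation tree inside a 192-voxel cube — seeded azimuths),
and a bolus angiography sequence (static background, linear ramp to a
peak frame, exponential washout, i.i.d. Gaussian noise, vessels darkening
as iodine absorbs). They deliberately do not model beam hardening,
detector noise spectra, cardiac/respiratory motion, cone-beam geometry,
or touching vessels. Passing tests on these phantoms therefore validate
the *measurement chain* — filter, scale selection, skeleton, calibration
algebra, FWHM — not robustness to every acquisition artifact of real
micro-CT.

The end-to-end recovery experiment runs a three-generation tree phantom
(root 40 px, child ratio 0.7, i.e. branch diameters 40/28/19.6 px — a
morphometrically plausible ratio that keeps every branch in the 5–50 px
range where integer scale quantization stays below ~15%) through the full
pipeline and regresses per-branch D_CT against ground truth. This is a
stand-in for the in vivo cross-validation against 2D angiography, which
cannot be reproduced without the original animals; the comparison
regression itself (`compare_dct_dang()`) is exercised on synthetic pairs.

## Numerical choices

* Gaussian kernels are FIR, truncated at 3σ, with symmetric (reflected)
  boundaries; smoothing matches `scipy.ndimage.gaussian_filter` to
  machine precision at the same truncation.
* Hessians are central differences of the smoothed volume (one-sided at
  borders), the standard discretization for this filter family.
* Eigenvalues use the closed-form trigonometric solver for symmetric 3×3
  matrices with a clamped `acos` argument; sorting is by absolute value.
* Argmax ties take the smallest scale; strict improvement is required to
  replace the incumbent.
* Problem sizes: the shipped calibration phantom is about 200 × 890 × 150
  voxels (comparable to a 256³ volume) and runs in minutes on one core
  thanks to the blocked separable convolution; the recovery experiment
  uses a 192³ tree. Both sizes are the package's default study
  conditions, chosen to keep the full diameter range 3.14–62.8 px with
  the spacing rule above.

## Known limitations

* S_MAX is quantized to the scale list; per-vessel D_CT inherits a ~3 px
  granularity with integer scales 1–30. Densifying the scale list reduces
  this at linear cost.
* The calibration slope absorbs the unstated filter constants (α, β, c,
  γ); with different constants the slope changes slightly but the
  linearity (R ≥ 0.99) is robust.
* Arteries and veins are not separated, airways are not removed, and
  loops (should any survive segmentation) are cut, not modelled.
* Parallel-beam projection ignores cone-beam divergence.
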