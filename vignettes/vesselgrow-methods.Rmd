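---
title: "Spectrum-guided branch-based vessel segmentation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrum-guided branch-based vessel segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselgrow)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, every tunable parameter with its units
and default, what the synthetic phantoms do and do not emulate, and the
places where the design was genuinely open and a choice had to be made.
It states no empirical result that the test suite does not itself
compute.

## 1. The segmentation model

The package targets *bright, roughly tubular structures on a darker
background* — vessels in fundus photographs or contrast CT. Four
assumptions run through all stages:

* vessel cross-sections are unimodal (approximately Gaussian) in gray
  level, brighter than their surroundings;
* vessels are locally straight at the scale of a region of interest, so
  their Fourier spectrum concentrates along one line;
* vessel trees are connected, so a single seed reaches the whole tree;
* gray levels live in (or are rescaled to) the 8-bit range 0–255.

Dark-vessel polarity (vessels darker than background) is out of scope:
the vesselness zero-branches (`lambda2 > 0`, and in 3D `lambda3 > 0`)
encode the bright polarity directly.

## 2. Hessian enhancement

`gaussian_hessian()` computes second derivatives by separable
convolution with sampled Gaussian-derivative kernels (kernel radius
`ceiling(4*sigma)`, reflect boundaries). Two numerical choices matter:

* **Scale normalization.** Derivatives are multiplied by σ² (the γ = 2
  convention). Without it, responses at σ = 1 and σ = 7 are not
  comparable and max-over-scales fusion would systematically prefer
  small scales.
* **Discrete-moment correction.** Sampled kernels are renormalized so
  the 0th-order kernel sums to 1 and the 2nd-order kernel has second
  moment exactly 2. At σ = 1 the raw sampled kernels are several
  percent off; the correction is what lets the center-pixel eigenvalues
  of Gaussian-profile phantoms match the closed form
  λ = −σ²·A/(w²+σ²)·(w²/(w²+σ²))^(n/2) to within the 5% oracle
  tolerance in the test suite.

**The structureness term.** The printed form of the vesselness uses the
scale symbol inside the noise-suppression factor, `1 − exp(−σ²/2c²)`,
while the accompanying text ties `c` to "half of the Frobenius norm" of
the Hessian. A factor that depends only on σ is constant across the
image and cannot suppress anything, contradicting its stated purpose, so
the default uses the per-pixel structureness `S = ||H||_F` with
`c` = half the image-wide maximum of `S` at that scale (the standard
second-order-structure reading). Both alternative readings remain
available: `structure_term = "scale"` for the literal form, and
`c_mode = "constant"` with an explicit `c` for a user-fixed normalizer.

**2D blobness.** The printed ratio involves λ₃, which does not exist in
2D; the unique dimension-consistent analogue |λ₁|/|λ₂| is used.

Parameter summary (all dimensionless unless noted):

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.5 | sensitivity of the 3D anisotropy term |
| `beta` | 0.5 | sensitivity of the blobness term |
| `scales` | 1, 3, 5, 7 (px) | Gaussian scales fused by per-pixel max |
| `c` | data-driven | structureness normalizer (gray levels) |

## 3. Spectral detection and orientation

`dft2()` uses the `1/(MN)`-scaled DFT (the printed exponent lacks the
imaginary unit; it is restored, since without it the transform is not a
Fourier transform). A Hann window is applied on the detection path to
keep image-boundary discontinuities from injecting axis-aligned spectral
lines.

`angular_energy_profile()` sums spectral measure over double wedges of
half-width ω (default 5°) on a Δθ = 1° grid. Several details were found
to matter and are worth recording:

* **Wedge symmetry.** A half-open wedge `[θ−ω, θ+ω)` includes a line at
  exactly θ₀ in the wedges θ₀ … θ₀+ω but only θ₀−ω+1 … on the other
  side, biasing the argmax upward by up to ω. Bin angles are therefore
  snapped to the Δθ grid and membership made symmetric; wedges with
  ω = Δθ/2 still tile the half-circle exactly.
* **DC exclusion radius 2 (Chebyshev).** Bins one or two steps from DC
  have angular quantization of 26–45° yet carry most of the magnitude
  for compact (Gaussian-profile) tubes; including them skewed
  orientation estimates by up to 8°.
* **Inscribed-disk restriction.** Corner bins exist only for diagonal
  directions; with them, even the *expected* white-noise profile bumps
  at 45°/135°. Restricting to the inscribed disk makes wedge areas
  equal (and drops the asymmetric Nyquist row/column of even-sized
  grids). `total` and the normalized profile refer to this off-DC,
  in-disk measure.
* **Sub-grid peak refinement.** The wedge argmax has a plateau of width
  ~ω around a strong line; the reported direction is the
  magnitude-weighted circular mean of raw bin angles within 1.5ω of the
  argmax. The window must exceed ω because the argmax itself can sit
  anywhere on the plateau. The suite verifies recovery within
  max(Δθ, 5°) on ≥ 95% of 240 tube phantoms.

**Detection (trough–peak–trough).** A vessel is declared when
`(Peak − Valley)/Distance ≥ threshold` on *both* sides of the global
peak. Two deliberate departures from the naive reading:

* **Troughs are the deepest flanking points** within the 90° arc on each
  side, not the nearest local minima. Real profiles carry micro-dips one
  grid step from the peak; "nearest local minimum" then yields distance
  1° and a meaningless slope (and a two-bin plateau yields slope ≈ 0).
  The formula itself is unchanged.
* **The detection statistic uses the power profile** (`|F|²`, which is
  what Parseval calls energy), while orientation estimation stays on
  `|F|`. On magnitude profiles, the angular anisotropy of a single
  white-noise realization overlaps the weakest tube responses and no
  threshold separates the populations; squaring concentrates tube
  energy and separates them by a factor of ~2.5.

**Threshold calibration.** The threshold has normalized-power-per-degree
units; no absolute value is meaningful a priori. The package default
(`vg_default_threshold()`, 0.0032) was fixed *once* by the prescribed
procedure — `calibrate_detection_threshold()` on 20 held-out tube and 20
noise phantoms at seed 42, taking the geometric mean of the weakest tube
slope and the strongest noise slope — and is never adjusted afterwards.
The acceptance suite checks ≥ 95% true-positive / ≤ 5% false-positive
rates on an *independent* 50 + 50 sample at this fixed value.

The printed direction-vector rule swaps vector components above 90°,
which is not a rotation; `direction_vector()` implements it literally as
the default and offers `formula = "continuous"` (`(cos θ, sin θ)`
throughout), which is what the pipeline uses internally — a cut
"perpendicular to the feature direction" is only perpendicular under the
continuous form.

## 4. Seed selection

The cross-section anchor is the maximum of the multiscale vesselness
inside the region of interest (falling back to raw gray without
enhancement) — the description of *where* along the vessel to cut is
otherwise open, and anchoring at the strongest tubular response
guarantees the cut crosses a vessel. The matched-filter width defaults
to half the anchor's argmax scale (the enhancement stage's own width
estimate); the Sobel threshold defaults to Otsu's method on the gradient
magnitude. Seeds must sit strictly inside the region of interest and
never on an edge pixel; candidates are taken in decreasing filter
response until one qualifies. Ties in all argmax operations break toward
the smallest row-major coordinate, for determinism.

## 5. Branch-based growing

Growth cycles expand the active front by a shell of radius `step`
(Chebyshev metric for 8/26-neighborhoods, Manhattan for 4/6). The
acceptance test `g ≥ μ − hσ` is applied together with hard
region-of-interest bounds `c_min ≤ g ≤ c_max`.

Design choices where the source material was open or contradictory:

* **Split connectivity at radius `step`.** Components of the new front
  are found under the growth neighborhood, but with adjacency radius
  equal to `step`: candidates arise within `step` of the old front, so
  two accepted pixels that close together belong to one advancing front.
  With radius 1 and step 2 the front fragments spuriously at the
  acceptance fringe — exactly the "excessive division" the widened
  neighborhood exists to prevent. The exported `detect_branches()`
  keeps radius 1 as its definition of connectivity.
* **Both components of a bifurcation become children.** The continuing
  component and the deferred ones all found new branches with the
  splitting branch as parent (largest continues, by count; ties to the
  smallest row-major coordinate). This is what makes a Y-junction read
  "trunk + two children" rather than "trunk continues, one child".
* **Reference level sequencing.** The thickness-linked reference
  `μᵢ = c_min + k·dᵢ` replaces the running mean once thickness is
  measurable (after a branch's third cycle). With the default `k = 0`
  the reference is thickness-free (= `c_min`) and is applied from the
  branch's first cycle: holding the stricter running-mean threshold for
  three cycles leaves a ring of rim pixels that get accepted cycles
  later as detached stragglers — each a spurious one-pixel branch.
* **`c_min` default.** Percentile-of-neighborhood rules proved
  unstable for Gaussian cross-sections (they land either near the
  background or near the peak depending on the window). The default is
  `background + exp(−1/2)·(peak − background)` with the background
  estimated by the image median and the peak by the 5×5 seed
  neighborhood maximum — the relative height at which a Gaussian
  profile crosses its nominal radius, i.e. the same level at which the
  phantoms' ground-truth masks are cut. `c_max` defaults to 255.
* **Reference-gray cap.** The printed capped branch `c_max + k·d_c` exceeds the
  8-bit range for plausible parameters and is discontinuous at `d_c`;
  whether `c_max` is a typo for `c_min` cannot be resolved from the
  source. The literal form is the default; `eq10_continuous = TRUE`
  substitutes `c_min`.
* **σ in the acceptance test.** Read as a running standard deviation
  over the branch's last 200 accepted pixels (reset at branch creation),
  floored at `sigma_min = 10` gray levels — a fresh branch has near-zero
  empirical spread, and an unfloored σ freezes growth at the seed's
  gray level. A constant-σ mode (`sigma_mode = "constant"`) covers the
  alternative "fixed gray-level difference" reading.
* **Thickness.** `dᵢ = 2 × mean(EDT − 0.5)` over the branch's pixels:
  twice the mean center-to-boundary distance. A 1-pixel line reports 1,
  a filled disk of radius r about 2r/3. (No affine rule can make both a
  1-px line report 1 *and* a width-w strip report w, because widths 1
  and 2 have identical center-sampled distance transforms; the
  convention above is fixed, documented, and only enters the growth
  when `k > 0`.)
* **Safety bound.** `max_cycles` defaults to the image diagonal; a
  truncated run is flagged, never silently completed.

## 6. The pipeline

`run_pipeline()` tiles the image into 64×64 regions with 50% overlap
(the region-of-interest size is otherwise unspecified; 64 px spans a
handful of vessel widths and gives the DFT enough support), detects per
tile, seeds every detecting tile, and grows from the single strongest
seed — vessel trees are connected, and one seed avoids stitching
artifacts. `--skip-enhancement` reproduces the reduced setting in which
detection and seeding run on raw gray. Inputs wider than 8 bits are
min–max rescaled to 0–255 by default. Reports embed the full parameter
set; timings are written to a separate file so that reruns with the same
configuration and seed are bit-identical.

## 7. What the phantoms emulate — and what they do not

The generators produce bright Gaussian-profile tubes (straight, Y, and
recursive binary trees; blob/sheet/tube volumes in 3D) on a uniform
background of gray 60, peak = background + contrast (default 100),
i.i.d. additive Gaussian noise, 8-bit clipping. Ground truth (mask =
pixels within the radius of the centerline; per-branch centerlines with
parent links) is computed before noise, and every generator is a pure
function of its parameters and seed.

Gaussian cross-sections were chosen over top-hat profiles because they
give the enhancement stage a closed-form oracle; the mask cut at the
width parameter then coincides with the `exp(−1/2)` relative-intensity
level that the growing stage's default `c_min` targets.

Deliberately *not* emulated: fundus texture, the optic disc, vessel
curvature and caliber variation along a branch, central light reflexes,
CT organ context, correlated or signal-dependent (Poisson/speckle)
noise. A green suite therefore establishes the algorithmic contracts —
oracle agreement, direction recovery, discrimination against white
noise, topology-exact growing, determinism — not clinical-grade accuracy
on real images, which additionally depends on contrast normalization and
denoising upstream of this package.

## 8. Known limitations

* Spectral analysis is 2D; volumes are handled slice-wise for detection
  and seeding (growing itself is natively 3D with 26-neighborhoods).
* The detection gate is a single-peak test: regions dominated by a
  junction of several comparable orientations can fail it even though a
  vessel is present (neighbouring tiles that see a single limb fire
  instead; the overlap tiling exists for this reason).
* The growing stage's `c_min` heuristic presumes unimodal bright
  cross-sections; vessels on a textured background need an explicit
  `c_min`.
* Wavelet-domain denoising, mentioned as an upstream step in the source
  material but never specified, is not implemented; the pipeline applies
  stages to the image as given.
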