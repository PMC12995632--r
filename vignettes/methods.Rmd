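---
title: "Methods: from serial sections to per-region genotype comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from serial sections to per-region genotype comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionquant)
```

## The problem

Transgenic reporter lines such as tau-GFP fusions under a gene promoter light
up both the cell bodies (somata) and the axons of the expressing population.
Mapping where a factor like Ebf2 is expressed across the postnatal brain, and
how a null mutation changes that expression, reduces to a concrete image
analysis and statistics problem: serial two-channel sections (reporter +
nuclear counterstain) must be aligned, segmented into somata and axons,
registered to a region label volume, summarized as per-region counts and
fluorescence, and compared between genotypes without pseudoreplicating
sections from the same animal.

`regionquant` implements that pipeline end to end, together with a synthetic
data generator with exact ground truth, so every stage is testable at desk
scale without microscopy data.

## Pipeline overview

1. **Synthetic data** (`generate_toy_atlas()`, `generate_section_stack()`,
   `apply_misalignment()`, `simulate_study()`) — two-channel 8-bit stacks
   with known soma positions, counts, axon centerlines, and rigid transforms.
2. **Preprocessing** (`rigid_align()`, `denoise()`, `rolling_ball()`,
   `downsample()`) — rigid stack alignment, median+Gaussian filtering,
   rolling-ball background subtraction, anti-aliased rescaling to a target
   pixel size (1.82 µm/px by default).
3. **Registration** (`estimate_affine()`, `map_points()`,
   `assign_regions()`) — affine mapping of stack coordinates into any
   integer-labelled volume; the Allen atlas is one possible input, never a
   dependency.
4. **Segmentation** (`tubularity()`, `segment_axons()`, `detect_somata()`)
   — Hessian-eigenvalue tubularity for axons; multi-scale
   Laplacian-of-Gaussian blob detection with marker-based watershed for
   somata, behind a pluggable detector interface.
5. **Quantification** (`count_by_region()`, `integrated_density()`,
   `cross_plane_consistency()`) — per-region count tables with explicit
   zeros, ROI integrated density (area × mean), and the
   all-three-planes positivity rule.
6. **Statistics** (`fit_random_intercept_lmm()`, `adjust_pvalues()`,
   `compare_regions()`, `percent_reduction()`) — a random-intercept linear
   mixed model per region with Satterthwaite degrees of freedom, Bonferroni
   and Benjamini–Hochberg correction across regions.
7. **3D rendering** (`build_volume()`, `export_volume()`) — aligned soma and
   axon layers stacked into anisotropic voxel volumes, exported as
   multi-page TIFF or NIfTI-1 for any external viewer.

## The statistical model

For each region $r$, the number of labelled somata in section $j$ of animal
$i$ is modelled on the identity scale as

$$y_{ij} = \beta_0 + \beta_g\,\mathrm{KO}_i + u_i + \varepsilon_{ij},
\qquad u_i \sim N(0, \sigma^2_a),\quad
\varepsilon_{ij} \sim N(0, \sigma^2_e),$$

with genotype as the fixed effect and animal identity as a random intercept.
Serial sections are repeated measurements of one animal, not independent
replicates; the random intercept absorbs the between-animal variance and
keeps the genotype test honest with 3 animals per group. A Gaussian linear
(not Poisson) model is used deliberately — it is the standard practice for
this kind of count comparison and what the field's mixed-model tooling fits —
and a log-count alternative is out of scope.

Estimation is REML. For a single random intercept both $\beta$ and
$\sigma^2_e$ profile out in closed form, leaving a one-dimensional criterion
in the variance ratio $\gamma = \sigma^2_a/\sigma^2_e$, which is minimized on
$[0, 10^6]$ by a coarse log-grid followed by golden-section refinement;
solutions that would require negative variance clamp to the $\gamma = 0$
boundary, where the fit reproduces ordinary least squares exactly and is
flagged `singular`. The genotype contrast is tested with a t statistic on
Satterthwaite denominator degrees of freedom, computed from the gradient of
the contrast variance with respect to $(\sigma^2_a, \sigma^2_e)$ and the
observed REML information (finite differences); at the boundary the residual
degrees of freedom $n - p$ are used. The unit tests cross-check $\beta$,
standard errors, variance components, degrees of freedom, p-values and the
REML criterion against `lmerTest`, which serves as an independent oracle and
never as the implementation.

Across regions, raw p-values are adjusted with both Bonferroni and
Benjamini–Hochberg (step-up FDR; via `p.adjust`), and significance stars
(`*` < 0.05, `**` < 0.01, `***` < 0.001) are assigned on the BH-adjusted
values. Effect sizes are reported as percent change
$100\,\beta_g/\beta_0$; `percent_reduction()` flips the sign and adds a
delta-method standard error.

For fluorescence intensity rather than counts, the same model applies with
the section plane available as an optional fixed covariate
(`covariates = "plane"`). Whether plane should enter as a fixed covariate or
another variance component is genuinely ambiguous in practice; the fixed
covariate is the simpler, documented choice.

## Image-processing choices

**Coordinate convention.** Pixels are (row, col) = (y, x), 0-based, centers
at integer coordinates; rotations are about the geometric image center.
Voxels of a label volume are half-open, $[v, v+1)$; a point exactly on the
upper face is outside. Working images are numeric matrices in [0, 255];
quantization to 8 bits happens only at export.

**Rigid alignment.** Neighbouring sections are registered pairwise
(mean-squared intensity difference, coarse grid plus Nelder–Mead over a
two-level pyramid) and the transforms are composed outward from a reference
section — chaining bounds the per-step motion, which is why serial sections
are aligned this way in practice. Two refinements matter for sub-pixel
accuracy and are worth recording:

* *Band-pass filtering.* The registration channel is filtered with a
  difference of Gaussians (sd 1.5 and 8 px) before matching. Uncorrelated
  pixel noise biases a least-squares registration toward half-pixel offsets
  (interpolation smooths the warped side's noise), and slowly varying
  background shifts the optimum wholesale; the band-pass suppresses both.
* *Symmetric refinement.* After chaining, every section is re-registered
  directly against the reference section with both images warped by half
  transforms. Warping both sides equalizes the interpolation noise budget,
  and registering to the reference (rather than through the chain) keeps
  per-section errors independent instead of accumulating as a random walk.
  On stacks that all share anatomy this is strictly better than pure
  chaining; on real data with slowly drifting anatomy the chained estimate
  remains the initialization, so the capture range is still set by
  neighbour similarity.

**Rolling-ball background.** The background is the envelope of a ball rolled
under the intensity surface — grayscale opening with a spherical-cap
structuring *function* (non-flat), which no installed image package
provides; the erosion/dilation kernel is therefore implemented in C++ and is
checked in the tests against a brute-force opening written directly from the
definition. The default radius is 50 px, the conventional choice for this
kind of data. Out-of-frame samples are ignored rather than padded.

**Tubularity.** The axon filter is the classical two-eigenvalue vesselness:
per scale $\sigma$, the scale-normalized ($\sigma^2$) Gaussian-derivative
Hessian gives eigenvalues $|\lambda_1| \le |\lambda_2|$, and bright ridges
($\lambda_2 < 0$) score
$\exp(-R_B^2/2\beta^2)\,(1 - e^{-S^2/2c^2})$ with $R_B = \lambda_1/\lambda_2$
and $S = \sqrt{\lambda_1^2+\lambda_2^2}$. Defaults: $\beta = 0.5$; $c$ is
half the maximum Hessian Frobenius norm, computed *globally across scales* so
that per-pixel argmax-scale selection remains meaningful (a per-scale
normalization washes out exactly the cross-scale contrast that scale
selection needs). The final map is the pixelwise maximum over scales,
rescaled to [0, 1]. No published constants exist for the original tool, so
these defaults are implementation choices, stated as such.

**Axon masks.** The response is thresholded (Otsu on the nonzero response by
default), components with skeleton length below a minimum (Zhang–Suen
thinning, implemented in the package since no installed package provides 2D
skeletonization) are removed, and an optional exclusion mask — the
deterministic, reproducible stand-in for manual false-positive removal — is
zeroed out last.

**Soma detection.** The built-in detector is classical rather than learned,
keeping the package self-contained: rolling-ball correction, multi-scale
scale-normalized LoG, 3×3 local maxima above `min_peak`, greedy seed
deduplication within about half a soma diameter (ties broken by response
then (y, x) order), a ridge veto that discards seeds whose local Hessian
eigenvalue ratio $|\lambda_1|/|\lambda_2| < 0.25$ (these are points on
axons, not somata), and marker-based watershed (`EBImage::propagate`) masks
grown inside an Otsu foreground, size-filtered to equivalent diameter in
[`d_min`, `d_max`] (defaults 4–20 px ≈ 7–36 µm at 1.82 µm/px). Any
learned segmenter can be plugged in as a function returning the same
detection table.

## What the synthetic data emulates — and what it does not

The generator is the package's test bed and defines the study conditions:

* **Counts.** Somata per region per section are Poisson with mean
  $\lambda_r \rho_r^{[\mathrm{KO}]}$; $\rho = 0.5$ models the halving of the
  labelled population seen in strong loss-of-function comparisons. No
  per-region count magnitudes are published for this system, so the default
  $\lambda = 25$ (and $\lambda = 15$ in the study-scale simulations, where
  five regions share a 96-px section) is the package's own choice of a
  realistic density for a strongly labelled nucleus at this resolution.
* **Animal heterogeneity.** Each animal's rates are scaled by a lognormal
  multiplier with 5% coefficient of variation — the between-animal variance
  component the random-intercept model exists to absorb, scaled to match the
  calibration of the statistical design (animal-level standard deviation 5
  at a control mean of 100).
* **Appearance.** Somata are isotropic Gaussian blobs (sd 3 px, peak
  180/255) with a hard-core minimum separation of 8 px enforced
  section-wide (somata are physical bodies; positions are resampled on
  conflict, never counts, so counts stay exactly Poisson). Axons are
  spline-smoothed random walks with a Gaussian tube profile (sd 1.5 px, peak
  120). The counterstain carries a smooth anatomy-following intensity
  pattern — per-region base brightness plus fixed bright landmarks shared
  across sections, the structural continuity that real serial sections have
  and that neighbour-based alignment relies on — plus sparse dim nuclei.
  The reporter channel receives only the diffuse (landmark-free) component
  as weak autofluorescence.
* **Noise.** Constant background (20), a smooth random field (amplitude 6,
  scale 25 px), Poisson shot noise, Gaussian read noise (sd 4), then
  rounding to 8 bits. With the default soma peak this gives a peak
  signal-to-noise ratio above 10.
* **Misalignment.** Per-section rigid perturbations drawn uniformly within
  stated bounds, recorded so alignment can be scored against the truth.

Not emulated: optical point-spread functions, chromatic aberration,
non-rigid tissue deformation, uneven illumination, staining gradients across
sections, or anatomically realistic region shapes (regions are boxes or
planar Voronoi cells extruded along z, so every section samples every
region). Passing tests therefore demonstrate algorithmic correctness under
controlled, idealized imaging physics — not performance on any particular
real dataset.

## Numerical choices and degenerate inputs

* Poisson placement at high density: the hard-core resampling gives up after
  200 attempts and keeps the draw, so counts are preserved even where the
  packing is infeasible; tests that require perfect separability use
  densities below the random-packing jamming limit.
* Blank (all-zero) sections get a warning and an identity transform;
  registration through them chains an identity pair.
* `rolling_ball()` with a radius exceeding both image dimensions warns and
  uses the global minimum as background.
* Region grids: `boxes` uses the most balanced integer factorization of
  `n_regions`; `voronoi` cells vary in area, which at fixed per-region
  $\lambda$ means variable density — the balanced geometry is the better
  choice for simulation studies.
* All randomness flows from one integer seed through a deterministic
  splitter (`derive_seed()`); no function perturbs the caller's RNG state.
* Simulation sizes in the test suite (e.g. 96–128 px sections, 5 stacks to
  50 simulated studies, 200–2000 statistical replicates) are chosen as the
  smallest designs at which the tested quantities have comfortable
  Monte-Carlo margins against their thresholds.

## A worked example

```{r example, eval = FALSE}
atlas <- generate_toy_atlas(c(8, 96, 96), 5, "boxes")
eff <- genotype_effect(lambda = 15, rho = c(1, 0.5, 1, 0.5, 1))
study <- simulate_study(atlas, eff, noise_spec(), seed = 1)
ana <- run_study_analysis(study$stacks, atlas, background_radius = 15,
                          d_min = 5, d_max = 12)
ana$comparison
autoplot(ana$counts)
autoplot(ana$comparison)
```

## Known limitations

* The intensity model's treatment of section plane (fixed covariate) is one
  of several defensible choices; random plane effects are not offered.
* Atlas registration is a single whole-stack affine (landmark least squares,
  with a best-effort intensity refinement); deformable registration and
  hierarchical region ontologies are out of scope.
* The built-in soma detector is tuned for blob-like somata on dark
  background; heavily overlapping cells merge (flagged only by mask area),
  and the ridge veto can drop somata sitting directly on bright axons.
* The cross-plane positivity rule is operational (≥ 1 detection or axon
  pixel per plane), replacing a visual judgement that cannot be encoded
  exactly.
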