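---
title: "Quantitative PET modelling in petquant: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative PET modelling in petquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`petquant` implements a complete quantitative PET chain — list-mode
processing, detector normalisation, an exact ray-traced forward model,
maximum-likelihood randoms, a voxel-driven single-scatter model, OSEM
reconstruction, iterative-Yang partial volume correction and bootstrap
uncertainty estimation — on parametrisable cylindrical scanner geometries.
This vignette is the package's own account of the science: the models, the
assumptions they rest on, the tunable parameters, the numerical choices,
and what the synthetic tests do and do not establish.

## 1. Scanner geometry and sinogram index algebra

A scanner is a stack of `n_rings` detector rings (pitch `ring_pitch` mm) on
a cylinder of diameter `ring_diameter` mm. Transaxially there are
`n_blocks_tx` blocks of `crystals_per_block` crystals; between blocks sit
`gaps_per_block` dead positions, so the ring has
`n_crystal_positions = n_blocks_tx * (crystals_per_block + gaps_per_block)`
positions and `n_angles = n_crystal_positions / 2` sinogram angles.

**Interleaved binning.** For a bin with angle index `a` and radial index
`r`, let `u = r - floor(n_radial_bins / 2)`. The bin belongs to the
half-angle class `c = 2a + p` whose parity `p` is opposite to the parity of
`u`; the crystal separation is `delta = n_pos/2 - u`, and the pair is
`k1 = ((c - 1 - delta)/2) mod n_pos`, `k2 = k1 + delta mod n_pos`. This is
the standard interleave: consecutive radial bins of an angle alternate
between the two native half-angle classes, and every bin corresponds to
exactly one unordered crystal pair (verified by exhaustive enumeration in
the tests). A bin is *active* when both its positions are live; with one
trailing dead position per 9-position block the 64-ring preset has 68516
active bins out of 344 x 252. The in-block position of the gap is a
convention (`gap_offset`, default trailing); the active-bin count is
invariant under rotating that convention.

**Axial algebra.** Plane ordering is segment-major (0, +1, -1, +2, -2, ...,
segment = signed ring difference band), within a segment ordered by
`r0 + r1`; the order is fixed so containers are bit-reproducible. For odd
span S, segment 0 covers `|RD| <= (S-1)/2` and each further segment the
next S ring differences, truncated at `max_ring_diff`; a stored plane
aggregates the span-1 planes of its segment sharing `r0 + r1` (group sizes
alternate 5 and 6 inside segment 0 for span 11). Single-slice rebinning
(SSR) collapses a pair to plane `r0 + r1`.

## 2. List-mode processing

Events carry (time, crystal A, crystal B, delayed flag). Histogramming
maps the transaxial pair through the bin map and the ring pair through the
Michelogram; events on dead positions or outside the radial/ring acceptance
go to a discard tally so counts are conserved exactly. Derived streams:
per-second head curve, per-second axial centre of mass of the prompts (the
motion proxy; computed from the SSR axial positions, a choice the package
makes since the profile basis is not otherwise constrained), the
time x bucket singles matrix, and delayed fan sums (each valid delayed
event increments both its crystals, so `sum_i d_i = 2 x` delayed count).

**Bootstrap.** The replicate draws n events with replacement from the n
originals — prompts and delayeds as one stream, each event keeping its
flag — and restores time order with a stable sort. Joint resampling was
chosen (over separate prompt/delayed resampling) because the delayed
stream's statistical weight relative to the prompts should itself vary
across replicates; the randoms estimate is then re-derived from each
replicate's own fan sums.

## 3. Normalisation

Per-bin factors multiply the *model* (never divide the data):
`geometric(radial) x interference(radial, in-block position of crystal A) x
eff(A) x eff(B) x axial(plane) x deadtime(bucket A) x deadtime(bucket B)`.
Dead positions have efficiency 0, which automatically inactivates their
bins. Dead time combines the paralysable and non-paralysable live-time
fractions as `exp(n tau_p) (1 + n tau_n)` with the bucket singles rate n
averaged over the frame; the composition order is a package convention (the
two-component model itself does not fix one).

Span-1 axial factors are decoded from span-S factors and a high-statistics
uniform acquisition: `eps1_uv = N_uv epsS_uv P1_uv / PS_uv`, with `N_uv`
the span-1 multiplicity of the group and P plane-summed counts. Scatter
needs its own axial factors because the block profile differs for oblique
scattered photons; they are formed as ratios of the SSR-predicted equal
share to the observed per-plane totals of the reference acquisition, and by
construction reproduce an SSR-consistent axial profile exactly.

## 4. Projector

The system matrix element `p_ij` is the exact 3-D Siddon intersection
length (mm) of LOR i with voxel j, with crystals modelled as points at the
face centres and half-open voxel intervals resolving boundary ties. The
2-D transaxial traversal is precomputed once per (angle, radial) bin as
parametric intervals `[t0, t1]` along the chord; because z is linear in the
same parameter, merging those intervals with the axial plane crossings of
any ring pair on the fly yields the exact 3-D lengths — equality with an
independently coded brute-force 3-D tracer is part of the suite, as are the
adjointness of the back projector (relative 1e-10) and chord-length
conservation (1e-9 mm). Ray tracing is always span-1; compressed sinograms
are formed by plane summation afterwards. Attenuation factors are
`exp(-sum_j p_ij mu_j / 10)` (mu in cm^-1, lengths in mm). No geometric
symmetries are exploited.

## 5. Randoms

With coincidence window `tau`, the randoms rate on a pair is
`R_ij ~ 2 tau S_i S_j`. The per-crystal singles rates are the
maximum-likelihood fixed point of the damped iteration
`S_i <- S_i/2 + (sum_j d_ij) / (2 sum_j 2 tau S_j)` over each crystal's
coincidence fan (transaxial acceptance x rings within the maximum ring
difference). Defaults: 10 iterations with early stop at fan-sum residual
1e-7; initialisation `sqrt(d_i / (2 tau F_i acq_time))` with `F_i` the fan
size (any positive start converges in the tests). At the fixed point the
modelled fan sums equal the measured ones, which is also why the estimate
is unbiased per axial profile while having far lower variance than the raw
delayeds. `tau` is a required scanner parameter (default 5.85 ns in the
presets, a realistic value for this scanner class; it cancels in the
randoms sinogram, which is fitted to the measured fan sums).

## 6. Voxel-driven single scatter

For an emission voxel E and a sampled detector A receiving the unscattered
photon, the probability of the opposite photon reaching a scattering patch
S is `P_i = eps_A exp(-int mu)` along the path from A through E to the
patch entry, with `eps_A = area cos(theta_inc) / (4 pi r_EA^2)` (point
detector, far field). The patch scatters with probability
`1 - exp(-mu_S l_S)` (patch = mu-map voxel above `patch_threshold`,
represented by its centre; `l_S` its chord). Scoring towards a sampled
detector B uses the unpolarised Klein-Nishina differential cross-section at
511 keV, `dsigma/dOmega = (r_e^2/2) P^2 (P + 1/P - sin^2 theta)` with
`P = 1/(2 - cos theta)` the scattered-energy fraction, the solid angle
`Omega_B = area cos(theta_B)/r^2`, and attenuation of the scattered photon
scaled by `c_B = mu_water(E')/mu_water(511 keV)` interpolated from a
standard water attenuation table (the medium is treated as water-like for
the energy scaling only). All ray integrals from voxels to sampled
detectors are precomputed in LUTs; the per-ray patch walk is exact grid
traversal. Contributions are weighted by voxel activity and binned on the
(A, B) LOR.

Defaults mirror routine brain-imaging practice: emission down-scaled 3x,
mu-map 2x, 1:8 axial and 1:7 transaxial detector sampling, emission
threshold 1% of the maximum, patch threshold 0.02 cm^-1 (captures all
tissue while skipping air).

**Interpolation.** The sampled detector pairs populate scattered sinogram
bins, not a regular grid. The package averages the sampled bins onto a
regular (radial node, angle node) subgrid per sampled ring pair, applies
separable natural cubic splines across radial and angle (the in-sinogram
"bicubic" step), and bilinear interpolation across the Michelogram
(r0, r1) ring grid; negative overshoot is clipped at zero and node values
are reproduced exactly. The aggregation-to-a-regular-grid step is a design
choice of this package; at full sampling the interpolation is skipped
entirely and the model output is exact, which is how the brute-force
equality test is run.

**Scaling.** One multiplicative factor per SSR axial group is fitted by
weighted least squares, `min sum w (prompts - randoms - k scatter)^2` with
`w = 1/max(prompts, 1)`, on the scatter-and-randoms-only mask
`AF > 0.95` (rays missing the object). This absorbs multiple scatter and
out-of-FOV scatter into the single-scatter shape. Both the mask threshold
and the weights are configuration with these defaults.

## 7. OSEM reconstruction

The acquisition model is `E[m_i] = n_i af_i (A x)_i + r_i + s_i`. The
subset update multiplies by the backprojected weighted ratio
`Abt_s[(n af) m / ((n af)(A_s x) + r + s)] / Abt_s(n af)` — one documented
algebra used everywhere, which avoids the classic misplacement of the
normalisation against the additive terms and is validated by noiseless
self-consistency. Defaults: 14 balanced interleaved subsets, 4 iterations,
scatter re-estimated from the current image before each iteration,
`epsilon = 1e-20` guarding divisions, no post-filter. Voxels the scanner
cannot see stay 0; with one subset the update is exactly MLEM. Ordered
subsets converge to a limit cycle rather than the ML point, so the
converged self-consistency figures in the tests (0.5% data RMS, 0.1%
count conservation) are demonstrated with MLEM iterations, while the
4 x 14 schedule is checked to land within a few percent.

## 8. Partial volume correction

Iterative Yang: starting from the observed image g, each iteration forms
regional means `a_i` over the parcellation (label 0, the background, is a
region too, so the surrogate covers the FOV), the piecewise-constant
surrogate `b = sum a_i I_i`, and updates `f <- g b / (h * b)` with 0/0
treated as 0. Ten iterations are the default. The PSF h is a separable
product of three 1-D two-Gaussian kernels (amplitudes and mm sigmas per
axis), sampled on the voxel grid, clipped non-negative and normalised to
unit sum; `fit_psf()` estimates the parameters from centred point-source
profiles by least squares with multi-start BFGS. All convolutions use
reflective boundaries (chosen; the method itself is boundary-agnostic) and
the separable implementation is verified against direct 3-D convolution to
1e-12. PVC is intended to run on the grid of the parcellation; regional
integrals are computed on that same grid.

## 9. Bootstrap uncertainty

`run_bootstrap()` re-runs a user-supplied reconstruction closure on R
list-mode replicates (seeds `base_seed + 1..R`), accumulating the voxel
mean and the across-replicate sample standard deviation (ddof = 1) — the
standard-error image — plus per-replicate regional SUVr values when a
parcellation and reference labels are given. Randoms are re-estimated from
each replicate's own delayeds; attenuation and scatter are recomputed by
the closure if it chooses to. Registration and parcellation variability
are out of scope (those inputs are fixed), so the reported uncertainty is
narrower than a full clinical chain's.

## 10. The synthetic world

The simulator emulates: expected trues = attenuated, efficiency-weighted
forward projection x duration; randoms from a per-crystal singles model
(singles proportional to crystal efficiency, scaled so the expected randoms
total is `randoms_fraction x` trues) with delayeds an independent Poisson
realisation of the same expectation, so the ML singles recovery is
genuinely testable; scatter as the package's own single-scatter shape
scaled to `scatter_fraction x` trues and restricted to live bins; Poisson
draws per bin converted to uniformly timed events; bucket singles records
every 2 s consistent with the randoms rates. Typical test settings use a
20 cm water cylinder, randoms and scatter fractions of 0.1-0.2, 5%
crystal-efficiency CV and 1e6-1e7 counts — values a phantom acquisition on
this scanner class would plausibly produce.

What the simulator does *not* emulate: positron range and non-collinearity,
multiple scatter and out-of-FOV scatter (the WLS scaling test injects a
known factor instead), pile-up beyond the two-component dead-time model,
vendor packet formats, and motion beyond piecewise-static source shifts. A
green end-to-end test therefore establishes internal consistency of the
full chain (model, corrections, reconstruction and uncertainty propagation
under Poisson statistics) — not agreement with any particular physical
scanner, which would require measured normalisation and Monte Carlo or real
phantom data.

## 11. Known limitations

* CPU only; the mMR-scale span-1 problem is representable but routine use
  is intended at reduced ring counts (the full 64-ring system is exercised
  for index algebra and projector identities, not full reconstructions).
* Time-of-flight, depth of interaction, non-cylindrical geometries and
  regularised reconstruction are out of scope.
* The scatter energy scaling treats the object as water-like; strongly
  bone- or metal-dominated objects would need a medium-resolved `c_B`.
* NIfTI support covers the package's own diagonal-affine files, not
  arbitrary third-party NIfTI variants.
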