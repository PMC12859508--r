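---
title: "Flicker spectroscopy of condensates and vesicles: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flicker spectroscopy of condensates and vesicles: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flickerspec)
```

## The physical model

A liquid-like droplet (a biomolecular condensate, or a vesicle) in
thermal equilibrium constantly deforms around its spherical mean shape.
The energy of a small deformation has two contributions: interfacial
tension $\sigma$ penalizes extra area, and bending rigidity $\kappa$
penalizes curvature. Writing the surface as
$r(\theta, \phi) = R\,(1 + \sum_{l \ge 2, m} u_{lm} Y_{lm}(\theta,\phi))$
and equating each quadratic mode's energy to $k_B T$ per equipartition,
the equilibrium variance of a surface mode of degree $l$ is

$$\langle |u_{lm}|^2 \rangle
  = \frac{k_B T}{\kappa\,(l+2)(l-1)\,[\,l(l+1) + \bar\sigma\,]},
  \qquad \bar\sigma = \frac{\sigma R^2}{\kappa}.$$

The reduced tension $\bar\sigma$ controls the crossover: for
$l(l+1) \ll \bar\sigma$ a mode is tension-dominated, above it
bending-dominated. The monopole ($l=0$, volume) and dipole ($l=1$,
translation) are excluded — the analysis removes them by normalization
and recentering.

A confocal microscope sees only a planar cross-section. On the equator,
the polar Fourier modes $V_q$ of the normalized in-plane radius inherit
the surface statistics:

$$\langle |V_q|^2 \rangle = \frac{k_B T}{\kappa}
  \sum_{l=q}^{l_{max}}
  \frac{N_{lq}^2 P_{lq}^2(0)}{(l+2)(l-1)\,[\,l(l+1)+\bar\sigma\,]},$$

where $N_{lq} P_{lq}(0)$ is the orthonormally normalized associated
Legendre function at the equator (zero whenever $l + q$ is odd). The sum
converges quickly; `l_max = 75` changes no mode by more than 0.1%
relative to `l_max = 150` for $\bar\sigma \in [1, 10^4]$ (tested).
`fit_spectrum()` fits $\bar\sigma$ and $\kappa$ to the measured spectrum
and recovers $\sigma = \bar\sigma \kappa / R^2$ from the measured mean
radius.

Because a real object can have a non-spherical *time-averaged* shape,
the static contribution is removed before fitting:
$|F_q|^2 = \langle |V_q|^2\rangle - |\langle V_q\rangle|^2$, where
$\langle V_q \rangle$ is the complex mean (averaging $|V_q|$ would not
cancel a static shape; the complex mean is the only reading under which
the subtraction is exact, and the one implemented).

## Pipeline and tunable parameters

1. **Detection** (`detect_centers`): difference of Gaussians with filter
   widths `min_size/(2*sqrt(2))` and `max_size/(2*sqrt(2))` (sizes are
   approximate object diameters in pixels); local maxima kept when the
   original pixel intensity exceeds `min_intensity` (fraction of the
   frame maximum, default 0.3). The DoG threshold is applied in
   intensity space, not response space — the response scale depends on
   the filter widths, the raw intensity does not.
2. **Extent** (`estimate_extent`): 4-connected flood fill above
   `fill_threshold` (default 0.5) of the object's *local* peak — local,
   not frame-wide, so background variation between cells is tolerated.
   The bounding box is padded by `max(5, 3*smoothing_width)` px so the
   whole interface profile is enclosed.
3. **Tracking** (`advance_tracker`): purely positional matching within
   `track_distance` (default 15 px), greedy in ascending distance with
   ties broken by detection index; a missing object survives
   `track_memory` (default 10) frames before its ID is retired.
4. **Boundary** (`build_field` + `trace_boundary`): Gaussian blur of sd
   `smoothing_width` (default 1.0 — keep it there unless the images are
   noisy), 5-point stencil derivatives $(1,-8,0,8,-1)/12$ (exact through
   quartics), directional gradient about the center; 400 rays, 15
   samples per pixel-width, 4-point Lagrange (4th-order) interpolation;
   per-ray argmax of the inward gradient (condensates) or of intensity
   (vesicles). The argmax is taken on the 15-per-pixel sample grid,
   matching the quoted 1/15-px resolution; no further refinement.
5. **Continuity** (`validate_contour`): any adjacent-ray radius jump
   above `continuity_max_step` (default 3 px, calibrated on a fused
   doublet fixture — the source material shows rejected shapes but no
   numeric rule) or any flagged ray rejects the frame.
6. **Spectrum** (`contour_modes`, `accumulate_modes`): exact geometric
   recentering (iterated first-Fourier-component shift + periodic
   re-sampling) kills $q=1$; normalization by the mean radius kills
   $q=0$; the DFT convention is two-sided with $1/N$ forward
   normalization. The convention and the simulator were defined jointly
   and verified against each other through the equipartition oracle —
   the convention is not stated by the source material, so the pair is
   fixed by that test.
7. **Fit** (`fit_spectrum`): error
   $\varepsilon=\sum_q \log_{10}^2(|F^{theo}_q|^2/|F^{exp}_q|^2)$ over
   $q = 2..15$; initialization on a log grid spanning 14 decades
   ($\bar\sigma \in 10^{-4..10}$, $\kappa \in 10^{-3..11}\,k_BT$, 8
   points per decade — the span is prescribed, the density is a package
   choice), then Nelder-Mead refinement in
   $(\log\bar\sigma, \log\kappa)$; the error surface has a single
   minimum, verified on a 200x200 grid. Unweighted residuals (the error
   definition is unweighted; SE-weighted fitting would be a variant, not
   implemented). Standard errors come from the linearized least-squares
   Jacobian. Residual diagnostics: Durbin-Watson on the per-mode log
   ratios in ascending $q$ (the residual definition and ordering are a
   package choice), and the tension-only comparison
   $\Delta\varepsilon = |\varepsilon(\sigma,\kappa) -
   \varepsilon(\sigma)|$ where the one-parameter model is the exact
   $\kappa \to 0$ limit, $\langle|V_q|^2\rangle = \frac{k_B T}{\sigma
   R^2}\sum_l N_{lq}^2 P_{lq}^2(0)/[(l+2)(l-1)]$.
8. **Population filters** (`apply_population_filters`): $\sigma >
   10^{-10}\,$N/m, continuity $> 60\%$, $\varepsilon < 0.5$,
   $\Delta\varepsilon > 0.03$, plus a minimum frame count (default 200,
   configurable downward for short videos). Durbin-Watson is recorded
   but carries no default threshold. Tension and rigidity are reported
   as geometric mean and geometric SD (they are log-normal across
   populations); other quantities as mean and SD.

Temperature is a required configuration value (default 298 K, a package
choice): the source material never states the temperature entering
$k_B T$, and the fitted parameters scale linearly with it.

## The smoothing-filter compensation

One correction implemented here deserves its own section. Smoothing the
image with a Gaussian of sd $\sigma_b$ before edge detection also
smooths the detected boundary *along the circumference*: angular
wavenumber $k = q/\bar R$ (pixels$^{-1}$) is attenuated in amplitude by
$e^{-k^2\sigma_b^2/2}$, hence mode power by
$e^{-q^2\sigma_b^2/\bar R^2}$. For a 15-px object at the default
$\sigma_b = 1$ that is $e^{-1}$ at $q = 15$: left uncorrected, the
high modes sag and the fitted rigidity absorbs the sag (in end-to-end
validation $\kappa$ came out roughly 3x high). Because the filter is
known exactly, `accumulate_modes(blur_sigma =)` multiplies the
accumulated spectrum by the inverse response; the exponent was verified
against measured attenuation at $\sigma_b = 0.5, 1.0, 1.5$ before being
adopted, and the correction is analytic — nothing in it is fitted. The
interface width itself ($\zeta \approx 0.8$ px) contributes no
comparable angular filtering at these radii.

## The synthetic world

`generate_video()` renders what the estimator assumes: quasi-spherical
droplets whose surface modes are drawn from the equilibrium distribution
above (`sample_shape`), cross-sectioned by the imaging plane
(`cross_section_contour`), painted with the tanh interface profile
$I(d) = \mathrm{bg} + A(\tfrac12 - \tfrac12\tanh((d - r(\phi))/\zeta))$
with $\zeta = 0.8$, plus additive Gaussian noise (sd 2% of the
amplitude) and 8-bit quantization. Defaults — amplitude 200/255,
background 10/255 — are chosen so the default detection parameters
succeed; all are configurable. Two deliberate modeling choices:

* **Frames are independent equilibrium samples.** No relaxation
  dynamics are modeled; the spectrum estimator only needs equilibrium
  statistics. Consequence: frame-rate effects cannot be simulated, and
  a green end-to-end test says nothing about temporally correlated
  noise.
* **Plane cuts are first-order in the mode amplitudes.** A fixed-height
  cut at offset $z_0 = R\cos\theta_0$ gives, to first order, in-plane
  radius $\rho(\phi) = R(\sin\theta_0 + u(\theta_0,\phi)/\sin\theta_0)$:
  the fluctuation is geometrically amplified by $1/\sin\theta_0$ off the
  equator. The simpler "surface radius at $\theta_0$" (without the
  $1/\sin\theta_0$) was considered and rejected: a confocal plane sits
  at fixed height, not at fixed polar angle. At the equator the two
  coincide, so every equator-based oracle is unaffected.

What the generator does **not** emulate: point-spread-function
convolution, photobleaching, z-drift, wetting, fusion, viscoelastic
(time-correlated) dynamics, and ring-profile (vesicle) rendering. Green
tests establish parameter recovery for bright, filled, free, in-focus,
equilibrium droplets — nothing more.

`simulate_contour_batch()` (and `simulate_spectrum_record()` built on
it) vectorizes the identical sampling mathematics over many shapes for
the Monte-Carlo oracles; it consumes the RNG in a different order than
repeated `sample_shape()` calls, so equivalence is established
distributionally through the equipartition oracle, not bitwise.

## Numerical choices and degenerate inputs

* Normalized Legendre functions: log-space closed form at the equator
  (stable far beyond $l = 75$), three-term normalized recurrence for
  off-equator arguments; the two agree to $10^{-10}$ and both match an
  independent small-$l$ recurrence oracle.
* Negative corrected mode powers (possible at finite sampling when the
  base shape dominates) are clamped to $10^{-3}\times$ the smallest
  positive mode and flagged via the `"clamped"` attribute; modes below
  the $1/15$-px resolution floor still enter the fit, as the fitted
  range $2 \le q \le 15$ is fixed.
* Rays start 1 px from the center and stop at the sub-image edge minus
  the stencil half-width; a ray whose maximum lands on either end-cap is
  flagged and fails the frame's continuity check.
* A flood-fill seed below the fill threshold is a degenerate extent: the
  object is skipped for that frame (counted as "unusable" by the
  parameter optimizer).
* All-zero residuals make Durbin-Watson 0/0: returned as NaN with a
  warning rather than silently 0.
* Tracker ties (two detections equidistant from one remembered object)
  resolve by lower detection index after sorting by distance; assignment
  is invariant under permutation of the detections.

## The parameter optimizer

`optimize_parameters()` tunes (`min_intensity`, `min_size`, `max_size`)
by lexicographic two-stage Bayesian optimization: stage 1 maximizes
$F_1$, the sum over sampled videos of the worst-frame usable-object
count; stage 2 maximizes $F_2$, minus the mean unusable count, subject
to retaining $F_1 \ge 0.9\,n_{max}$. "Usable" means detected with
non-degenerate extent and a continuity-passing boundary; "unusable"
means detected but failing either (the source material leaves these
undefined; the downstream filters define them here). The surrogate is a
squared-exponential GP on the unit box with the length scale chosen
from a small grid (0.05-0.4) by marginal likelihood at every refit — a
fixed length scale either over-smooths count plateaus or under-smooths
trends — and expected-improvement acquisition over a seeded 500-point
candidate cloud, 10 random initial designs, 40 evaluations per stage;
kernel, acquisition and budget are package choices — the source
material names none. The stage-2 constraint is enforced by an additive
penalty proportional to the usable-count deficit (5 per missing
object): a cliff penalty would flatten the surrogate near the feasible
boundary, exactly where the optimum sits. Stage 2 warm-starts from the
cached stage-1 evaluations, and the returned parameters are the best
*strictly feasible* evaluated point, so the retention constraint holds
exactly on the stored subset.
`fill_threshold` and `smoothing_width` are deliberately outside the
optimization box.

## Known limitations

* The tension estimate carries the cut-radius bias off-equator: at 0.34
  radii the measured radius is $0.94 R$, contributing $\sim +13\%$ to
  $\sigma$ before any fitting error; the off-equator acceptance run
  measures the total bias and finds the medians below 20%.
* Detection noise sets a white floor under the high modes; the
  base-shape correction removes the static part of the boundary bias
  but not the per-frame noise.
* No PSF model: real confocal optics blur more than a 1-px Gaussian;
  on real data the smoothing-filter compensation uses the configured
  `smoothing_width` only and does not attempt to estimate the optical
  transfer function.
* Single-channel, TIFF/OME-TIFF input only; proprietary formats must be
  converted upstream.
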