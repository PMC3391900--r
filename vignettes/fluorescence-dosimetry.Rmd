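---
title: "Fluorescence dosimetry of riboflavin diffusion in the cornea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluorescence dosimetry of riboflavin diffusion in the cornea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribodosim)
```

## The measurement problem

Corneal cross-linking (CXL) stiffens the corneal stroma by soaking it with
riboflavin (vitamin B2) and irradiating with 365 nm UVA. The treatment's
photochemistry depends on how much riboflavin has reached each depth of the
cornea, yet standard protocols prescribe fixed soak times and doses for all
eyes. Because the cornea is transparent and riboflavin fluoresces, a camera
viewing a projected UVA slit from the side records a cross-sectional image of
the riboflavin distribution: depth-resolved *fluorescence dosimetry*.
`ribodosim` implements the analysis chain for such images — from raw frames to
diffusion-coefficient estimates — together with a fully seedable synthetic
generator of those frames, so the whole chain is testable without laboratory
data.

## The transport model

Soaking is modelled as one-dimensional diffusion into a semi-infinite medium
held at a constant boundary concentration. Fick's second law then gives

$$C(x, t) = C_0 \left(1 - \operatorname{erf}\frac{x}{2\sqrt{D t}}\right),$$

with $x$ the corneal depth, $t$ the soak time, $D$ the diffusion coefficient
and $C_0$ the boundary concentration. Riboflavin fluorescence is linear in
concentration over the working range, so the same functional form holds for
the recorded intensity with $C_0 \to I_0$ (detector counts). `erf_profile()`
evaluates this model; depths are carried in micrometres and $D$ in
cm$^2$/s, with the single unit conversion applied inside the model.

Two properties of this solution anchor the test suite: the profile depends on
depth only through $x/\sqrt{Dt}$ (so $(D, t)$ and $(D/4, 4t)$ generate
identical profiles and a fit with a mis-declared time rescales $\hat D$
exactly), and the boundary value is pinned at $C_0$ for all $t > 0$.

For an intact epithelium the cornea is biphasic: a thin cellular barrier
(epithelium, nominal thickness 75 µm here) with diffusivity an order of
magnitude below the stroma's. `layered_profile()` and `fit_two_layer()`
treat the two layers as *independent* semi-infinite media: the epithelial
segment runs from the surface with its own $(C_1, D_1)$, and the stromal
segment restarts its depth origin at the top of the stroma with its own
$(C_2, D_2)$. No continuity of value or flux links the segments; they share
only the soak time. We chose the origin-reset convention because $C_2$ is
defined as the boundary intensity at the *top of the stroma*; a shared
surface origin would make $C_2$ a surface extrapolation instead. A
consequence worth knowing: a single-medium profile with its origin at the
surface is *outside* the stromal segment's model family (a shifted erf is
not an erf), so fitting two layers to truly single-layer, surface-origin
data attenuates $\hat D_2$ systematically. Degeneracy of the two-layer fit —
$D_1 \approx D_2$ within joint standard errors — holds exactly when the
no-contrast data respect the segment-wise convention (equal parameters in
both segments), and that is how the degeneracy tests are constructed.

## The numerical oracle

`pde_oracle()` integrates $\partial C/\partial t = \partial_x (D(x)\,
\partial_x C)$ with an explicit, flux-conservative finite-difference scheme
(fixed boundary value at $x = 0$, zero initial condition, far Dirichlet zero
boundary placed at $8\sqrt{D_{\max} t}$ so the domain is effectively
semi-infinite). It exists to *check* the analytic model, never to fit. The
default time step uses a Courant ratio $r = D\,\Delta t/\Delta x^2 = 0.25$,
half the explicit stability limit; the solver refuses a step beyond the
limit and reports the largest stable one. We deliberately avoid $r = 1/6$,
where the leading truncation terms cancel: at $r = 0.25$ the observed
convergence is cleanly second order in $\Delta x$, which is itself one of
the properties under test. At a 1 µm grid the solution agrees with the erf
profile to better than $10^{-6}$ of the boundary value — three orders below
the $10^{-3}$ bar the tests assert.

Note that the continuous two-layer PDE solution and the two-part erf fit are
*different models* near the layer boundary (the PDE enforces flux
continuity; the fit does not), so the suite compares them only qualitatively
(a low-diffusivity barrier suppresses deep concentration), never pointwise.

## What the synthetic generator emulates

`render_slit_image()` produces the frame the dosimetry camera would record:

* geometry — 12.2 µm/px image-plane calibration; camera at 45° to the
  surface normal, so depth along an image column appears foreshortened by
  $\cos 45°$; a circular-arc corneal leading edge (radius 8500 µm, a typical
  anterior curvature — only the edge shape matters, and the porcine radius
  is not otherwise constrained); a projected slit one pixel (~25 µm) wide;
* signal — `baseline + gain × C(depth)` under the arc in the slit columns,
  with fluorescence linear in concentration and boundary intensities around
  190 counts, i.e. ~80% of 8-bit saturation;
* noise — Gaussian read noise (1% of range, 2.55 counts, in the noisy study
  conditions) plus optional Poisson shot noise, applied before rounding and
  clipping to [0, 255];
* determinism — every generator is a pure function of (spec, seed); series
  renderers derive per-frame seeds from the spec seed, and control frames
  are rendered with their own seed so baseline subtraction faces independent
  noise, as two camera exposures would.

The generator does **not** model light scattering or absorption along the
excitation path, optical point spread, perspective, defocus, eye movement,
or saturation nonlinearity. Passing round trips therefore demonstrate that
the analysis chain is self-consistent and unbiased *under the stated image
formation model* — not that it is robust to the optics of a real bench.

The consumption generator adds first-order photobleaching in delivered UVA
dose: frame $k$ scales the fluorescent concentration by
$\exp(-k_b\,\mathrm{dose}_k)$, uniform over depth (optional exponential
depth attenuation is off by default). The bleach-rate default
$k_b = 0.05\,(\mathrm{J/cm^2})^{-1}$ was fixed once so that a full
10.8 J/cm$^2$ exposure bleaches roughly 40% of the near-surface signal — a
clearly detectable but not saturating effect; the underlying kinetics are
not otherwise constrained. A parallel zero-rate control series mirrors the
unirradiated control eyes.

The Franz-cell generator evaluates the classical membrane-permeation
solution under sink conditions, whose late-time asymptote is
$Q(t) \to A\,(D C_d / h)\,(t - h^2/6D)$ with lag time $h^2/6D$ (~44 s for a
100 µm flap at $D = 3.8\times10^{-7}$ cm$^2$/s), plus optional Gaussian
assay noise.

## The analysis pipeline and its conventions

`image_to_profile()` composes four steps, each exported on its own:

1. **Baseline subtraction** against the pre-riboflavin control frame, clipped
   at zero (negative fluorescence is unphysical and the intensity model
   assumes $I \ge 0$).
2. **Surface detection**: per slit column, the first row along the
   penetration direction exceeding half the column maximum, refined
   sub-pixel by linear interpolation; a valid edge requires a sub-threshold
   pixel above it, so uniform frames raise a no-signal error rather than a
   spurious surface.
3. **Profile extraction**: intensity averaged across the strip width,
   sampled row by row from the first whole row at or below the detected
   edge; that row is depth 0. Anchoring on a whole row makes noise-free
   round trips exact to quantization.
4. **Cosine correction**: true depth = apparent depth / $\cos(\theta)$,
   under the convention that the 12.2 µm/px calibration is an image-plane
   measurement; the generator shares the convention, and it is recorded in
   the metadata rather than asserted as the bench's own.

Fits use Levenberg–Marquardt least squares (via `minpack.lm`) with a
positivity bound on $D$ and deterministic starts: $I_0$ from the surface
sample and $D$ from the half-intensity depth via
$D_{\text{init}} = (x_{1/2} / 2\,\mathrm{erf}^{-1}(0.5))^2 / t$. The soak
time is fixed, not fitted — $D$ and $t$ enter only as $Dt$ and are not
jointly identifiable from one profile. Profiles are trimmed to the window
from the surface to the depth where intensity first falls below 2% of the
surface value, keeping the data in the semi-infinite regime and away from
the posterior boundary, which the model does not represent. Non-converged
fits are returned flagged, never dropped; aggregation (`aggregate_fits()`)
is an unweighted mean and sample SD over converged fits inside the 6–21
minute soak-time window, with excluded fits counted.

## Dosimetry conventions

`cumulative_dose()` sums irradiance × duration with
J/cm$^2$ = (mW/cm$^2$)/1000 × s; the two protocol totals (3 mW/cm$^2$ ×
30 min = 5.4 J/cm$^2$; six 1-minute segments at 30 mW/cm$^2$ =
10.8 J/cm$^2$) are exact. The consumption metric is the mean intensity in
the top 12 µm of *true* (cosine-corrected) depth; at the bench sampling
(~17.3 µm true spacing) that is exactly the surface sample, and the result
is flagged `single_sample` accordingly. Drops are percentages relative to
index-matched controls, which removes the diffusion-only drift (riboflavin
keeps diffusing inward between checkpoints even without UVA). The null
(zero-bleach) noise floor is assessed with three eyes pooled per arm,
matching the consumption experiment's n = 3 treated / n = 3 control design;
with single eyes per arm the single-pixel metric's floor is a few percent
rather than the sub-2% the pooled design achieves.

## Franz-cell analysis

`steady_state_flux()` regresses $Q$ on $t$ over the last 50% of samples
(the window fraction is configurable; the choice is conventional, not
data-driven), guarded by a lag-time check: a rough diffusivity from the
full-series slope must leave at least 4 window samples past $h^2/6D$. A
flat series legitimately yields zero flux; a net-decreasing one is
rejected, while small noisy dips pass (strict per-step monotonicity would
reject valid noisy data). `diffusivity_ficks_first()` applies
$D = J h / C_d$ under the sink approximation (receiver concentration
neglected in the driving gradient — standard Franz-cell practice).
Published magnitudes for riboflavin through corneal flaps, a few
$10^{-7}$ cm$^2$/s, serve as plausibility ranges only; recovering them
would require the physical experiments.

## Problem sizes and numerical choices

The test suite and the acceptance script run the pipeline at the bench
geometry (220 × 64 px frames), 20 noise seeds for median-recovery
statistics, 100 profile-level replicates for the bias/coverage property,
12 seed pairs (×3 eyes per arm) for the null consumption floor, and PDE
grids of 8/4/2 µm for the convergence order plus a single 1 µm run for the
agreement bound. These sizes make every Monte-Carlo summary stable to well
within the tolerances asserted while keeping a full run in the tens of
seconds.

Degenerate inputs are first-class: flat profiles raise a non-identifiability
error, profiles with fewer than 5 points (or 5 per segment in the biphasic
fit) are rejected with segment-specific errors, a boundary depth beyond the
data raises the stromal-segment error, and a missing control frame is an
error because baseline subtraction is mandatory.

## Known limitations

* The optical simplifications listed above: no scattering, absorption, PSF,
  or perspective. Real-bench estimates will carry systematic effects the
  round trips cannot see.
* The two-part biphasic fit is a descriptive convention, not a solution of
  the two-layer PDE; its coefficients are effective per-segment values.
* The epithelial segment spans only ~5 pixels at the bench sampling, so
  $\hat D_1$ carries several-percent noise at 1% image noise — the layered
  recovery tolerance (10%) is accordingly wider than the single-layer one
  (5%).
* The photobleaching law is the simplest consistent with detectable
  consumption; no depth attenuation or oxygen kinetics.
* Soak-time-dependent boundary concentration (drop instillation schedules)
  is not modelled; $C_0$ is constant during a soak.
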