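---
title: "Methods: Monte Carlo photon transport in a schematic eye with drusen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo photon transport in a schematic eye with drusen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drusim)
```

## The problem

Drusen are extracellular deposits that form beneath the retinal pigment
epithelium (RPE) and are an early marker of age-related macular
degeneration. At early stages they are hard to see in conventional fundus
images, but scanning-laser-ophthalmoscope dark-field ("retro-mode")
images are sensitive to them — for reasons that are not obvious from the
image alone. `drusim` simulates the underlying light transport: a narrow
laser beam enters a schematic eye, scatters and is absorbed in the
retinal layers (and in a druse, when present), and part of it returns
through the pupil. The question the simulation answers is whether the
*shape* of the reflected beam, observed outside the eye, carries usable
information about a druse tens of micrometres across sitting hundreds of
micrometres deep in the retina.

## Transport model

Photons are transported one at a time, analog style: no statistical
weights, no roulette. Each photon terminates in exactly one of four
ways — bulk absorption, absorption at the surface of a material with no
refractive index (the iris), exit through the world boundary, or the
scatter cap — and the per-run ledger
`generated = absorbed_bulk + absorbed_boundary + world_exit + capped`
is checked exactly on every run. Analog transport is the natural match
for the study design, which counts discrete photons on detector planes.

Within a material, the absorption free path and the scattering free path
are sampled independently from exponentials with the material's
`ABSLENGTH` and `RAYLEIGH` mean free paths, and the shorter of the two
competes against the distance to the nearest volume boundary. Sampling
two exponentials and taking the minimum is equivalent to sampling one
exponential at the total attenuation and choosing the interaction channel
with probability $\mu_a/(\mu_a+\mu_s')$; the equivalence is asserted in
the test suite.

Scattering uses the Rayleigh-type phase function
$p(\cos\theta) \propto 1 + \cos^2\theta$, sampled by exact inversion of
its cubic CDF, with uniform azimuth. This phase is symmetric (mean cosine
zero, variance $2/5$); the strong forward anisotropy of real tissue is
carried entirely by using the *reduced* scattering coefficient
$\mu_s' = (1-g)\,\mu_s$ as the scattering rate. The anisotropy parameter
$g$ is therefore stored only as documentation and never enters the
kernel; no Henyey–Greenstein sampling is performed.

Boundaries apply unpolarized Fresnel reflectance (mean of the s and p
coefficients), with probabilistic splitting: a uniform draw against
$R(\theta_i, n_1, n_2)$ decides specular reflection versus Snell
refraction, and total internal reflection occurs beyond the critical
angle. A material with no refractive index terminates photons at its
surface; in the bundled table only the iris behaves this way. All
retinal layers, the druse and the vitreous share index 1.337, so no
Fresnel reflections occur inside the retina — scattering and absorption
alone distinguish the layers, and druse detectability cannot be an
artifact of an index step at its surface.

### Optical constants

The bundled table (`default_material_table()`) fixes each tissue's
$\mu_a$, $\mu_s'$, refractive index, and the derived mean free paths at
the single 2 eV (~620 nm) operating point. Orange light is the practical
choice for fundus work because RPE absorption is comparatively low there.
Values are stored exactly as tabulated in the source data (druse
coefficients arrive in cm$^{-1}$ and are converted at load; all internal
lengths are mm); the reciprocal-coefficient round trip is tested to
0.5%. Because the optical constants alone drive transport, the chemical
composition of the media is deliberately not modelled.

## Scene geometry

The eye is a priority-ordered list of axis-aligned solids: point location
returns the highest-priority volume containing a point, so later volumes
carve earlier ones. This replaces constructive solid geometry: a layer
listed after the body it lines simply claims its region. The ray tracer
stops at the first surface where the located volume changes, then nudges
the photon $10^{-6}$ mm forward and relocates; that constant is the only
geometric tolerance in the kernel.

Default dimensions (all config-overridable):

| element | default |
|---|---|
| scleral globe | outer radius 12 mm, wall 0.8 mm |
| cornea | spherical cap shell, outer radius 7.8 mm, thickness 0.55 mm |
| anterior chamber depth | 3.05 mm |
| pupil / iris | 4 mm aperture in an absorbing annulus |
| crystalline lens | ellipsoid, 9 mm equatorial diameter, 3.7 mm thick |
| retinal layers | ILM 2 µm, NR 200 µm, RPE 10 µm, choroid 250 µm |
| ora serrata | layers truncated 60° from the posterior pole |

Two geometric choices deserve explanation. First, the corneal apex
protrudes 0.3 mm beyond the scleral sphere (the anatomical corneal
bulge). With internally tangent spheres the incident beam would cross a
few-micrometre sliver of *sclera* — a strong scatterer — before reaching
the cornea, scattering several percent of the beam at a nonphysical
junction; the protrusion removes that artifact at the cost of a 24.3 mm
axial length. Second, the iris is a cylindrical annulus (a tube solid)
rather than a sphere section, because a flat annular diaphragm cannot be
built from spheres and ellipsoids without boolean operations.

The lens vertex radius implied by the 9 × 3.7 mm ellipsoid
($a^2/c \approx 10.9$ mm) is flatter than a living crystalline lens, so
the eye focuses slightly behind the retina; at the 350 µm beam aperture
the resulting geometric spot on the retina is ~50–65 µm FWHM, consistent
with the intended ~50 µm focus. The test suite asserts a [30, 80] µm
band rather than an exact value, since the spot size is a consequence of
the schematic-lens choice, not a tuned input.

Drusen are placed on the optical axis at the posterior pole, at four
depths that follow their growth history: `A` centered mid-NR, `B` apex
touching the ILM–NR boundary, `C` base touching the NR–RPE boundary, and
`D` entirely beneath the RPE on the choroid side. The catalog spans
spheres of 50/100/150 µm, a 150 × 100 µm oblate ellipsoid, a 100 µm
cube, and a row of three 100 µm spheres.

## Beam and scan

The source is a collimated circular beam with a Gaussian transverse
profile, FWHM 350 µm ($\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$), born
2 mm in front of the corneal apex and aimed along $-z$. The 2 mm
stand-off places the source behind the incident-beam reference detector
at +1.74 mm, so that plane sees the full beam; a 1 mm stand-off would
put the source inside it. The beam carries no divergence of its own —
focusing arises entirely from the simulated refractive surfaces.

A scan is five runs tilted about the source point in the y–z plane so
the chief rays strike the retina at $\{-2,-1,0,+1,+2\}\times$
`scan_step` (default 50 µm, the radius of the reference druse). The tilt
angles are calibrated by deterministic refraction-only ray tracing
through the actual scene, with a secant refinement that absorbs the
small aberration nonlinearity at the outer runs; a tilt whose chief ray
no longer reaches the retina (iris clipping) is rejected before any
transport. Run 2 is frontal incidence on the druse; runs (1,3) and (0,4)
are mirror pairs, and for a y-symmetric scene their detector images
mirror statistically — which run of a mirror pair is "first" is a pure
labeling convention of scan direction.

## Detectors

Ten transparent planes normal to the optical axis tally crossings into
200 × 200 grids: `DA` (2 × 2 mm, 1.74 mm before the cornea) and `DB`
(0.28 × 0.28 mm, 106 µm before the retina) record the incident ($-z$)
beam; `D1` (2 × 2 mm, 556 µm before the retina, inside the vitreous)
and `D2`–`D8` (8.5 × 8.5 mm at 1–9 cm outside the cornea) record the
reflected ($+z$) beam. "Distance from the retina" is measured from the
inner ILM surface on the axis. Detectors never interact — seed-matched
runs with and without them produce identical photon fates — and binning
is half-open with the top edge closed, so grid files round-trip
bit-exactly. `D5` at 3 cm is the analysis station: nearer planes see a
tightly focused spot, farther ones a dispersed one.

## Profile analysis

A detector grid is collapsed to a profile by taking, for every y row,
the *maximum* count over x. The profile is smoothed with a natural cubic
smoothing spline under the `csaps` parameter convention: minimize
$p\sum_i (h_i - f(i))^2 + (1-p)\int f''^2$, so $p = 1$ interpolates and
$p = 0$ degenerates to the least-squares line; the default is
$p = 0.01$. The abscissa is the *bin index* (spacing 1). This choice
matters: with the abscissa in mm the same $p$ smooths the 8.5 mm-station
profile with an equivalent bandwidth of ~1.4 mm, which flattens the
druse-induced flank asymmetry to below 3% at any photon budget —
irreconcilable with the 25–30% deviations the analysis is designed to
expose — while the index convention (the natural one when smoothing a
200-pixel histogram) preserves it.

On each flank of the smoothed peak, the analysis walks outward from the
peak to the first crossing of 40% of the baseline-subtracted peak
height, fits an ordinary least-squares line through the 21 smoothed
samples centered there, and forms the asymmetry deviation from the left
slope $d_1 > 0$ and right slope $d_2 < 0$:

$$y = d_1/|d_2| - 1 \;\; (d_1 \ge |d_2|), \qquad
  y = d_2/d_1 + 1 \;\; (d_1 < |d_2|).$$

$y$ is zero iff the flanks are equally steep, positive when the left
flank is steeper (excess photons on the right side), and exactly changes
sign under a mirror reflection of the grid; it is invariant under count
rescaling. The baseline subtraction (curve minimum) makes the 40% anchor
robust to a uniform background and reduces to the plain definition when
the background is ~0. Flanks too short for the 21-point window are
truncated symmetrically and flagged. Slopes are fitted to
spline-evaluated (not raw) points, so the regression sees exactly the
curve the smoothing step produced.

## Statistical behaviour at scaled-down budgets

Full-scale runs of this study design use $2\times10^7$–$2\times10^8$
photons per run — tens of CPU-hours. The package defaults scale this by
~100: $2\times10^6$ per run for the outside station,
$2\times10^5$ for the inner one, a few minutes total on one CPU. Count
*fractions* and *ratios* are budget-invariant up to binomial error and
reproduce at these budgets. The asymmetry statistic is different: at
$2\times10^6$ photons the outside-station peak expectation is ~10 counts
per bin, the row-max profile is Poisson-sparse, and the flank-slope
noise gives a per-run standard deviation of $y$ of roughly 0.2–0.4.
Since the noise scales as $1/\sqrt{N}$, the same pipeline at the
full-scale budget has $\sigma_y \approx 0.02$–0.04, i.e. null
deviations safely below the 10% level that frames the statistic's
uncertainty. At the
scaled-down budget the druse signal ($|y| \sim 0.3$ on the lateral runs)
is therefore detectable but individual runs are noisy, and null-band
assertions at the ~10% level should be read as full-budget properties.
The acceptance checks report the scaled-down values as measured.

A second quantitative sensitivity is worth knowing: the fraction of
druse-backscattered light collected *outside* the eye scales with the
pupil's solid angle seen from the retina — roughly with the pupil
diameter squared — while the inside-detector ratios bypass the pupil
entirely. A 6 mm (pharmacologically dilated) pupil collects ~2.25× more
druse signal at the outside station than the default 4 mm one. The 4 mm
default is the standard undilated schematic value; users reproducing
dilated imaging conditions should override `pupil_diameter`.

## What the synthetic fixtures do and do not show

`generate_fixture()` builds 200 × 200 grids with a controllable Gaussian
spot — amplitude, center, width, uniform background, a flank-dependent
width multiplier (`skew`) and Poisson noise — so the profile analysis is
testable in isolation from the transport. Fixtures exercise the
*analysis*: branch signs, mirror antisymmetry, scale invariance,
smoothing limits. They do not emulate the correlated, non-separable
structure of real reflected beams (halo around a specular core, iris
vignetting), so fixture-based passes validate the statistic, not the
optics; the transport tests and scan-level checks cover the rest.

## Numerical choices

* Geometry nudge $10^{-6}$ mm after every crossing; candidate surfaces
  per step are restricted to the current volume plus higher-priority
  volumes with overlapping bounding spheres.
* RNG: a 64-bit Mersenne Twister seeded through a splitmix64 scramble,
  with uniforms built from the high 53 bits, so streams are reproducible
  bit-for-bit across platforms; each scan run uses the substream
  `master_seed * 64 + run_index`, recorded in the manifest.
* Scatter cap $10^5$ per photon (fate `capped`, always reported, never
  silently dropped); in practice unreached — the strongly scattering
  media (RPE, druse, sclera) are also absorbing enough that walks
  terminate within tens to hundreds of steps.
* Smoothing-spline solve: dense symmetric system
  $(I + \lambda Q R^{-1} Q^\top)f = h$ at $n = 200$; peak ties resolve
  to the smallest index; `p = 0` and `p = 1` short-circuit to the exact
  limits.
* Chief-ray calibration tolerance $10^{-5}$ mm at the retina, at most 8
  secant iterations.

## Limitations

Beyond the scaled-budget statistics above: no polarization, coherence,
or wavelength dependence (single 2 eV operating point); no blood
vessels; no aspheric or gradient-index lens, accommodation, or pupil
diffraction; detectors are ideal transparent planes, not a confocal
detection path; the exact rotation vectors, detector conventions and
all-volume dimensions of the reference geometry are not published, so
banded agreement rather than point equality is the appropriate
expectation when comparing detector statistics across implementations
of this design.
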