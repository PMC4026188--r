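# drusim

Analog Monte Carlo simulation of a laser beam traversing a schematic
human eye, with and without retinal drusen, plus the reflected-beam
profile analysis used to ask a clinical question: **can a druse — a
deposit tens of micrometres across buried under the neurosensory
retina — be detected from outside the eye by the shape of the reflected
beam?** Drusen are an early marker of age-related macular degeneration,
and scanning-laser-ophthalmoscope retro-mode images are empirically
sensitive to them; this package simulates the photon transport that
explains why.

## What it simulates

* **Scene** — a nested-volume schematic eye (cornea, aqueous humor,
  absorbing iris with a 4 mm pupil, 9 × 3.7 mm ellipsoidal lens,
  vitreous, ILM/NR/RPE retinal layers, choroid, sclera) in an air-filled
  world box, with optional drusen (spheres, ellipsoid, cube, or sphere
  sets; four depths from sub-RPE to sub-ILM) at the posterior pole.
* **Optics** — per-material absorption coefficient µa and reduced
  scattering coefficient µs′ (mm⁻¹) at the single 2 eV (~620 nm)
  operating point, converted to the mean free paths that drive
  transport; refractive indices for Fresnel/Snell boundary physics. All
  retinal layers and the druse share the vitreous index (1.337), so no
  reflections occur inside the retina.
* **Transport** — analog (unweighted) photon tracking: competing
  exponential free paths for absorption and scattering, the Rayleigh
  (1 + cos²θ) phase function sampled by exact CDF inversion, unpolarized
  Fresnel splitting with total internal reflection, terminal absorption
  at materials without a refractive index, world-boundary kill, and an
  exact per-run conservation ledger.
* **Scan** — a collimated 350 µm FWHM Gaussian beam, five runs tilted so
  the chief rays strike the retina at −100, −50, 0, +50, +100 µm around
  the druse site (calibrated by deterministic ray tracing through the
  eye's refractive surfaces).
* **Detectors** — ten transparent 200 × 200 tally planes: DA/DB for the
  incident beam, D1 (inside the eye) and D2–D8 (1–9 cm outside the
  cornea) for the reflected beam.
* **Analysis** — per-Y max-over-X profile histograms, a cubic smoothing
  spline in the csaps convention (p = 0.01), 21-point flank-slope
  regressions at 40% peak height, and the asymmetry deviation
  y = d₁/|d₂| − 1 (d₁ ≥ |d₂|) or d₂/d₁ + 1 (d₁ < |d₂|), which is zero
  for a symmetric reflected beam and flips sign under mirror reflection.

## Worked example

Five-run scans of the druse-free eye ("S0") and of an eye carrying a
100 µm spherical druse at intermediate retinal depth ("S1"), 200 000
photons per run, comparing the inner reflected-beam detector D1:

```r
library(drusim)

s0 <- scenario("S0", n_photons = 2e5, seed = 7, detectors = c("D1", "D5"))
s1 <- scenario("S1", druse = list(shape = "b", position = "A"),
               n_photons = 2e5, seed = 7, detectors = c("D1", "D5"))
r0 <- run_scenario(s0)
r1 <- run_scenario(s1)

compare_runs(lapply(r0$grids, `[[`, "D1"), lapply(r1$grids, `[[`, "D1"))
```

```
  run n_without n_with    ratio increase_pct   y_without     y_with
1   0     11632  12430 1.068604     6.860385  0.47252485  0.1250553
2   1     11543  33694 2.918999   191.899853 -0.07713736 -1.7218658
3   2     11678  57394 4.914711   391.471142  0.15276384  0.2978762
4   3     11674  33427 2.863372   186.337159  0.42303908  0.4767513
5   4     11782  12439 1.055763     5.576303 -0.20072253  0.3520435
```

Reading the table: when the beam focuses on or beside the druse (runs
1–3), the number of photons reflected back to the inner detector rises
roughly 3–5-fold (`ratio`), because the druse's scattering mean free
path (0.0243 mm) is far shorter than the surrounding neurosensory
retina's (1.333 mm): photons entering it are redirected toward the
detector instead of dying in the strongly absorbing RPE behind it. At
the scan edges (runs 0 and 4) the beam misses the druse and the two
scenes agree to within a few percent. The y columns are the flank
asymmetry of each beam profile; at this reduced photon budget they are
noisy (see the methods vignette for the noise scaling), while the count
ratios are already stable.

Outside the eye the same druse raises the D5 detection fraction from
about 2.7% of the generated beam to about 3.0% at frontal incidence —
the druse is visible, though attenuated, through the pupil:

```r
vapply(r0$grids, function(g) detection_fraction(g$D5), numeric(1))
#> [1] 2.6980 2.7665 2.7355 2.7485 2.7195
vapply(r1$grids, function(g) detection_fraction(g$D5), numeric(1))
#> [1] 2.6735 2.8525 2.9605 2.8615 2.7185
```

A thin command-line front end with verbs `simulate`, `analyze`,
`compare`, `fixture` and `validate` is installed at
`inst/scripts/drusim`.

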