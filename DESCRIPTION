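Package: drusim
Title: Monte Carlo Photon Transport in a Schematic Human Eye for Retinal
    Drusen Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analog Monte Carlo simulation of a low-energy (2 eV) Gaussian
    laser beam traversing a schematic human eye, with and without retinal
    drusen. Provides a nested-volume eye geometry (cornea, aqueous humor,
    iris, crystalline lens, vitreous humor, retinal layers, choroid,
    sclera) with per-material absorption and reduced-scattering mean free
    paths, Rayleigh-type (1 + cos^2 theta) scattering, Fresnel/Snell
    boundary physics, virtual 200 x 200 detector planes inside and outside
    the eyeball, a five-run angular scan of the retina, and a reflected
    beam-profile analysis (cubic smoothing spline, flank slope regression,
    and the left/right asymmetry deviation statistic) used to assess
    whether sub-retinal drusen are detectable from outside the eye.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
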