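# Analog transport physics: free paths, phase function, Fresnel boundaries,
# conservation

test_that("free-path sampling matches the exponential closed form", {
  x <- sample_free_path(1e6, 4.0, seed = 3)
  expect_lt(abs(mean(x) - 4.0), 0.012)  # LLN: 3 sigma of the sample mean
  expect_lt(abs(sd(x) - 4.0), 0.02)
  # process absent in the material: infinite path, the process never wins
  expect_identical(sample_free_path(5, NA), rep(Inf, 5))
  expect_error(sample_free_path(5, -1), "> 0")
})

test_that("competing absorption/scattering exponentials behave like a single
           total-attenuation draw with a Bernoulli channel choice", {
  la <- sample_free_path(2e5, 2.0, seed = 10)
  ls <- sample_free_path(2e5, 0.5, seed = 11)
  step <- pmin(la, ls)
  mfp_tot <- 1 / (1 / 2.0 + 1 / 0.5)
  expect_lt(abs(mean(step) - mfp_tot), 0.003)
  # channel probability mu_a / (mu_a + mu_s')
  p_abs <- mean(la < ls)
  expect_lt(abs(p_abs - (1 / 2.0) / (1 / 2.0 + 1 / 0.5)), 0.005)
})

test_that("scattering cosines follow the (1 + cos^2) phase", {
  # exact inverse-CDF checks via injected uniforms
  expect_equal(sample_scatter_cosine(u = 0.5), 0, tolerance = 1e-12)
  expect_equal(sample_scatter_cosine(u = c(0, 1)), c(-1, 1), tolerance = 1e-9)
  mu <- sample_scatter_cosine(1e6, seed = 12)
  expect_true(all(mu >= -1 & mu <= 1))
  expect_lt(abs(mean(mu)), 0.002)            # symmetric density: E = 0
  # quadrature oracle for the variance of the phase cosine
  v_oracle <- stats::integrate(function(m) m^2 * phase_function_density(m),
                               -1, 1)$value
  expect_equal(v_oracle, 0.4, tolerance = 1e-8)
  expect_lt(abs(mean(mu^2) - v_oracle), 0.002)
  # goodness of fit in 50 equal-width bins
  br <- seq(-1, 1, length.out = 51)
  obs <- table(cut(mu, br))
  pr <- diff((3 * br + br^3 + 4) / 8)  # phase CDF differences per bin
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = pr / sum(pr)))
  expect_gt(gof$p.value, 0.01)
})

test_that("Fresnel reflectance matches closed forms", {
  expect_equal(fresnel_reflectance(0, 1, 1.5), 0.04, tolerance = 1e-12)
  expect_equal(fresnel_reflectance(0.3, 1.4, 1.4), 0)   # index matched
  # beyond the critical angle: total internal reflection
  crit <- asin(1 / 1.337)
  expect_equal(fresnel_reflectance(60 * pi / 180, 1.337, 1.0), 1)
  expect_lt(fresnel_reflectance(crit - 0.01, 1.337, 1.0), 1)
  # grazing incidence tends to full reflection from either side
  expect_gt(fresnel_reflectance(89.9 * pi / 180, 1, 1.5), 0.98)
})

test_that("boundary events split, bend, and absorb correctly", {
  n <- c(0, 0, 1)
  d <- c(sin(0.4), 0, -cos(0.4))
  # forced refraction (u above R): Snell's law for the transmitted angle
  ev <- boundary_event(d, n, n1 = 1, n2 = 1.5, u = 0.999)
  expect_identical(ev$event, "refracted")
  sin_t <- sqrt(sum(ev$direction[1:2]^2))
  expect_equal(sin_t, sin(0.4) / 1.5, tolerance = 1e-12)
  # forced reflection: specular mirror about the normal
  ev2 <- boundary_event(d, n, n1 = 1, n2 = 1.5, u = 0)
  expect_identical(ev2$event, "reflected")
  expect_equal(ev2$direction, c(sin(0.4), 0, cos(0.4)), tolerance = 1e-12)
  # index matched: never reflects, direction unchanged
  ev3 <- boundary_event(d, n, n1 = 1.337, n2 = 1.337, u = 1e-9)
  expect_identical(ev3$event, "refracted")
  expect_equal(ev3$direction, d, tolerance = 1e-12)
  # entering a material with no refractive index: absorbed at the border
  ev4 <- boundary_event(d, n, n1 = 1.337, u = 0.5)
  expect_identical(ev4$event, "absorbed_at_boundary")
  # contract violations
  expect_error(boundary_event(d, c(0, 0, 2), 1, 1.5, u = 0.5), "unit")
  expect_error(boundary_event(d, -n, 1, 1.5, u = 0.5), "oppose")
})

test_that("Monte Carlo reflected fractions track the Fresnel curve", {
  set.seed(21)
  for (pair in list(c(1, 1.5), c(1.337, 1))) {
    for (th in c(0, 0.3, 0.6, 0.9, 1.2)) {
      R <- fresnel_reflectance(th, pair[1], pair[2])
      nrep <- 2000
      u <- runif(nrep)
      frac <- mean(u < R)
      tol <- 3 * sqrt(max(R * (1 - R), 1e-4) / nrep)
      expect_lt(abs(frac - R), tol + 1e-12)
    }
  }
})

test_that("a pure absorber slab transmits e^-1 at one absorption length", {
  mats <- slab_materials(test_material("Absorber", mu_a = 0.5))  # mfp 2 mm
  sc <- slab_scene("Absorber", thickness = 2)
  det <- detector("T", z = -5, side_lengths = 80, filter = "-z")
  run <- simulate_run(sc, list(det), origin = c(0, 0, 5),
                      direction = c(0, 0, -1), fwhm_um = 0,
                      n_photons = 2e4, seed = 8, materials = mats)
  frac <- run$grids$T$n_crossings / 2e4
  expect_lt(abs(frac - exp(-1)), 3 * sqrt(exp(-1) * (1 - exp(-1)) / 2e4))
  expect_true(conservation_ok(run))
})

test_that("materials without bulk processes are crossed ballistically", {
  # cornea-like slab: refractive index only, no abslength/rayleigh
  mats <- slab_materials(test_material("Clear", rindex = 1.0))
  sc <- slab_scene("Clear", thickness = 10)
  rec <- propagate_photon(sc, c(0, 0, 20), c(0, 0, -1), materials = mats,
                          seed = 2)
  expect_identical(rec$fate, "world_exit")
  expect_identical(rec$n_scatters, 0L)
  expect_equal(rec$z, -60, tolerance = 1e-6)  # crossed the whole world
})

test_that("an empty world passes photons straight to the world boundary", {
  sc <- scene(list(volume("World", shape_box(30, 30, 30), c(0, 0, 0), "Air")))
  mats <- material_table(list(test_material("Air")))
  rec <- propagate_photon(sc, c(0, 0, 0), c(0, 0, 1), materials = mats)
  expect_identical(rec$fate, "world_exit")
  expect_equal(rec$path_mm, 30, tolerance = 1e-9)
})

test_that("photons reaching the iris are absorbed at its border", {
  eye <- cached_eye()
  # pencil beam aimed at the iris annulus, outside the pupil: apart from
  # the few percent Fresnel-reflected at the cornea, all photons terminate
  # on the iris surface
  run <- simulate_run(eye, list(), c(3, 0, 2), c(0, 0, -1), fwhm_um = 0,
                      n_photons = 400, seed = 5)
  expect_gt(run$fates[["absorbed_boundary"]] / 400, 0.9)
})

test_that("a conservative scattering slab loses no photons (R + T = 1)", {
  mats <- slab_materials(test_material("Scatterer", mu_s = 1))  # no absorption
  sc <- slab_scene("Scatterer", thickness = 40)
  run <- simulate_run(sc, list(), origin = c(0, 0, 5),
                      direction = c(0, 0, -1), fwhm_um = 0,
                      n_photons = 2000, seed = 13, materials = mats)
  f <- run$fates
  expect_identical(unname(f["world_exit"]), 2000)
  expect_identical(unname(f["absorbed_bulk"] + f["absorbed_boundary"] +
                            f["capped"] + f["lost"]), 0)
})

test_that("the fate ledger balances exactly and runs are seed-reproducible", {
  eye <- cached_eye()
  dets <- default_detectors(eye)[c("DA", "D1", "D5")]
  r1 <- simulate_run(eye, dets, c(0, 0, 2), c(0, 0, -1), 350, 5000, seed = 77)
  r2 <- simulate_run(eye, dets, c(0, 0, 2), c(0, 0, -1), 350, 5000, seed = 77)
  expect_true(conservation_ok(r1))
  expect_identical(r1$fates, r2$fates)
  for (nm in names(r1$grids))
    expect_identical(r1$grids[[nm]]$counts, r2$grids[[nm]]$counts)
  r3 <- simulate_run(eye, dets, c(0, 0, 2), c(0, 0, -1), 350, 5000, seed = 78)
  expect_false(identical(r1$grids$DA$counts, r3$grids$DA$counts))
})

test_that("detector tallies never alter transport (transparency)", {
  eye <- cached_eye()
  dets <- default_detectors(eye)
  with_d <- simulate_run(eye, dets, c(0, 0, 2), c(0, 0, -1), 350, 4000,
                         seed = 31)
  no_d <- simulate_run(eye, list(), c(0, 0, 2), c(0, 0, -1), 350, 4000,
                       seed = 31)
  expect_identical(with_d$fates, no_d$fates)
})
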