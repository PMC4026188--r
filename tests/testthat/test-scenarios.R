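# Scenario catalog, end-to-end runs, fixtures, config round-trips

test_that("the druse catalog spans the six documented geometries", {
  expect_equal(druse_catalog("a")[[1]]$shape$params, 0.025)
  expect_equal(druse_catalog("b")[[1]]$shape$params, 0.05)
  expect_equal(druse_catalog("c")[[1]]$shape$params, 0.075)
  expect_equal(druse_catalog("d")[[1]]$shape$params, c(0.075, 0.075, 0.05))
  expect_equal(druse_catalog("e")[[1]]$shape$params, c(0.05, 0.05, 0.05))
  f <- druse_catalog("f")
  expect_length(f, 3)
  expect_true(all(vapply(f, function(e) e$shape$params, numeric(1)) == 0.05))
})

test_that("every catalog shape builds at every depth position", {
  for (id in c("a", "b", "c", "d", "e", "f")) {
    for (pos in c("A", "B", "C", "D")) {
      scn <- scenario("t", druse = list(shape = id, position = pos),
                      n_photons = 1e4)
      setup <- drusim:::scenario_setup(scn)
      expect_s3_class(setup$scene, "scene")
    }
  }
})

test_that("scenario configs round-trip losslessly through YAML", {
  scn <- scenario("S1", druse = list(shape = "b", position = "A"),
                  beam = beam_spec(fwhm_um = 350, n_photons = 12345,
                                   scan_step_um = 50),
                  detectors = c("D1", "D5"), seed = 99,
                  geometry = list(pupil_diameter = 5))
  path <- tempfile(fileext = ".yml")
  write_scenario_config(scn, path)
  back <- read_scenario_config(path)
  expect_identical(back$name, scn$name)
  expect_identical(back$druse$catalog_id, "b")
  expect_identical(back$druse$position, "A")
  expect_equal(back$geometry$pupil_diameter, 5)
  expect_equal(back$beam[names(back$beam)], scn$beam[names(scn$beam)])
  expect_identical(back$detectors, c("D1", "D5"))
  expect_identical(back$seed, 99)
  # explicit shape objects survive too
  scn2 <- scenario("S", druse = list(shape = shape_ellipsoid(0.075, 0.075, 0.05),
                                     position = "C"), n_photons = 1e4)
  write_scenario_config(scn2, path)
  back2 <- read_scenario_config(path)
  expect_equal(back2$druse$shape$params, c(0.075, 0.075, 0.05))
  unlink(path)
})

test_that("run_scenario produces balanced, reproducible, single-peaked runs", {
  scn <- scenario("smoke", n_photons = 2e4, seed = 123,
                  detectors = c("DB", "D1"))
  res <- run_scenario(scn)
  expect_length(res$grids, 5)
  for (k in 1:5) {
    f <- res$fates[[k]]
    expect_equal(f[["generated"]],
                 f[["absorbed_bulk"]] + f[["absorbed_boundary"]] +
                   f[["world_exit"]] + f[["capped"]])
    expect_equal(f[["lost"]], 0)
  }
  # reflected-beam profile on D1 is single-peaked away from the boundary
  pc <- smooth_profile(profile_histogram(res$grids[[3]]$D1))
  peak <- which.max(pc$smoothed)
  expect_gt(peak, 20); expect_lt(peak, 180)
  # determinism: identical master seed, byte-identical grids
  res2 <- run_scenario(scn)
  for (k in 1:5)
    expect_identical(res2$grids[[k]]$D1$counts, res$grids[[k]]$D1$counts)
  # summary table covers every run x detector pair
  expect_equal(nrow(res$summary), 10)
})

test_that("scan runs mirror in y for the y-symmetric druse-free eye", {
  scn <- scenario("sym", n_photons = 2e4, seed = 321, detectors = "DB")
  res <- run_scenario(scn)
  peak_y <- vapply(1:5, function(k) {
    g <- res$grids[[k]]$DB
    w <- colSums(g$counts)  # y-marginal of the incident spot
    y <- profile_histogram(g)$y_positions
    sum(w * y) / sum(w)     # count centroid: robust spot center
  }, numeric(1))
  # incident spots walk up in y and mirror pairwise around the center run
  expect_true(all(diff(peak_y) > 0))
  expect_lt(abs(peak_y[1] + peak_y[5]), 0.005)
  expect_lt(abs(peak_y[2] + peak_y[4]), 0.005)
  expect_lt(abs(peak_y[3]), 0.005)
})

test_that("unphysical configs fail before transport", {
  expect_error(run_scenario(scenario("tiny", n_photons = 1e3)),
               "photon budget")
  scn <- scenario("clip", n_photons = 1e4,
                  beam = beam_spec(scan_step_um = 5000))
  expect_error(run_scenario(scn), "configuration error")
  expect_error(scenario("bad", druse = list(shape = "b")), "position")
})

test_that("scenario outputs round-trip through the output directory", {
  out <- file.path(tempdir(), "drusim-out")
  scn <- scenario("io", n_photons = 1e4, seed = 11, detectors = "D1")
  res <- run_scenario(scn, out_dir = out)
  files <- list.files(out)
  expect_true(all(sprintf("io_run%d_D1.txt", 0:4) %in% files))
  expect_true("io_summary.csv" %in% files)
  expect_true("io_manifest.yml" %in% files)
  g <- read_detector_grid(file.path(out, "io_run2_D1.txt"))
  expect_identical(g$counts, res$grids[[3]]$D1$counts)
  man <- yaml::read_yaml(file.path(out, "io_manifest.yml"))
  expect_identical(man$scenario, "io")
  expect_length(man$run_seeds, 5)
  cfg <- read_scenario_config(file.path(out, "io_config.yml"))
  expect_identical(cfg$name, "io")
  unlink(out, recursive = TRUE)
})

test_that("fixture generation honours its spec and determinism", {
  g1 <- generate_fixture(200, 1.1, skew = 1, seed = 5)
  g2 <- generate_fixture(200, 1.1, skew = 1, seed = 5)
  expect_identical(g1$counts, g2$counts)
  # symmetric spot: asymmetry near zero (Poisson noise only)
  expect_lt(abs(analyze_grid(g1)$y), 0.15)
  # zero amplitude: the empty-profile flag propagates
  g0 <- generate_fixture(0, 1, background = 0, seed = 1)
  expect_true(profile_histogram(g0)$empty)
  expect_error(analyze_grid(g0), "empty")
  expect_error(generate_fixture(100, -1), "sigma")
})
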