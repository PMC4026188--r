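#' Druse shape catalog
#'
#' The six simulated druse geometries:
#' * `"a"` sphere, diameter 50 um
#' * `"b"` sphere, diameter 100 um (the reference druse)
#' * `"c"` sphere, diameter 150 um
#' * `"d"` oblate ellipsoid, major (lateral) diameter 150 um, minor
#'   (axial) diameter 100 um
#' * `"e"` cube, side 100 um
#' * `"f"` set of three 100 um spheres in a row along the scan (y) axis,
#'   centers 100 um apart
#'
#' @param id Catalog letter `"a"`..`"f"`.
#' @return A list of druse entries (shape + lateral offset), ready for
#'   the `drusen` argument of [build_eye()] once a `position` is added.
#' @export
druse_catalog <- function(id = c("a", "b", "c", "d", "e", "f")) {
  id <- match.arg(id)
  one <- function(shape, offset = c(0, 0)) list(shape = shape, offset = offset)
  switch(id,
    a = list(one(shape_full_sphere(0.025))),
    b = list(one(shape_full_sphere(0.05))),
    c = list(one(shape_full_sphere(0.075))),
    d = list(one(shape_ellipsoid(0.075, 0.075, 0.05))),
    e = list(one(shape_box(0.05, 0.05, 0.05))),
    f = list(one(shape_full_sphere(0.05), c(0, -0.1)),
             one(shape_full_sphere(0.05), c(0, 0)),
             one(shape_full_sphere(0.05), c(0, 0.1))))
}

#' Define a simulation scenario
#'
#' A scenario bundles everything one five-run scan needs: the eye
#' geometry (with an optional druse from the catalog), the beam, the
#' active detector stations, the photon budget and the master seed.
#' The druse-free scenario is the baseline ("S0"); the 100 um sphere at
#' position A is the reference druse scenario ("S1").
#'
#' @param name Scenario identifier.
#' @param druse `NULL` for the druse-free eye, or a list with `shape` (a
#'   catalog letter `"a"`..`"f"` or a [shapes] object) and `position`
#'   (`"A"`..`"D"`, see [build_eye()]).
#' @param geometry Eye-geometry overrides (see [eye_defaults()]).
#' @param beam A [beam_spec()].
#' @param detectors Character vector of station names to activate
#'   (subset of DA, DB, D1..D8), or `"all"`.
#' @param seed Master seed; per-run kernel streams are derived from it.
#' @param max_scatters Per-photon scatter cap.
#' @return An object of class `"scenario"`.
#' @examples
#' s0 <- scenario("S0", n_photons = 1e5)
#' s1 <- scenario("S1", druse = list(shape = "b", position = "A"),
#'                n_photons = 1e5)
#' @export
scenario <- function(name, druse = NULL, geometry = list(),
                     beam = NULL, detectors = "all",
                     n_photons = NULL, seed = 1, max_scatters = 1e5) {
  if (is.null(beam)) beam <- beam_spec()
  if (!is.null(n_photons)) beam$n_photons <- as.integer(n_photons)
  if (!is.null(druse)) {
    if (is.null(druse$position)) stop("druse entry needs a 'position' (A-D)")
    if (is.character(druse$shape)) {
      druse$catalog_id <- druse$shape
    } else if (!inherits(druse$shape, "shape")) {
      stop("druse 'shape' must be a catalog letter or a shape object")
    }
  }
  structure(list(name = name, druse = druse, geometry = geometry,
                 beam = beam, detectors = detectors, seed = seed,
                 max_scatters = max_scatters),
            class = "scenario")
}

# resolve the druse entry of a scenario into build_eye()'s drusen list
scenario_drusen <- function(scn) {
  if (is.null(scn$druse)) return(NULL)
  entries <- if (!is.null(scn$druse$catalog_id)) {
    druse_catalog(scn$druse$catalog_id)
  } else {
    list(list(shape = scn$druse$shape, offset = c(0, 0)))
  }
  lapply(entries, function(e) {
    e$position <- scn$druse$position
    e
  })
}

# build the scene + detector set a scenario describes
scenario_setup <- function(scn, materials = default_material_table()) {
  sc <- build_eye(geometry = scn$geometry, drusen = scenario_drusen(scn),
                  materials = materials)
  dets <- default_detectors(sc)
  if (!identical(scn$detectors, "all")) {
    missing <- setdiff(scn$detectors, names(dets))
    if (length(missing)) stop("unknown detector station(s): ",
                              paste(missing, collapse = ", "))
    dets <- dets[scn$detectors]
  }
  list(scene = sc, detectors = dets)
}

#' Run a scenario
#'
#' Executes the full five-run angular scan of a [scenario()]: builds and
#' validates the scene, calibrates the scan directions through the eye's
#' refractive surfaces, runs the transport kernel once per run with a
#' seed substream derived from the master seed, and collects the
#' detector grids, fate ledgers and a per-run summary. Optionally writes
#' every grid as a plain-text file plus a YAML manifest (config, seeds,
#' fate ledger, config hash) for reproducibility.
#'
#' @param scn A [scenario()].
#' @param materials A [material_table()].
#' @param out_dir Directory for grid/manifest output (`NULL` = keep
#'   results in memory only).
#' @param record Per-run number of leading photons to record in full.
#' @return An object of class `"scenario_result"`: `grids[[run]][[det]]`
#'   ([detector_grid()]), `fates[[run]]`, `summary` (data frame of run x
#'   detector counts and fractions), `directions`, the scenario and the
#'   scene.
#' @export
run_scenario <- function(scn, materials = default_material_table(),
                         out_dir = NULL, record = 0) {
  stopifnot(inherits(scn, "scenario"))
  if (scn$beam$n_photons < 1e4)
    stop("photon budget too small (need >= 1e4 per run)")
  setup <- scenario_setup(scn, materials)
  dirs <- run_directions(setup$scene, scn$beam, materials)
  n_runs <- scn$beam$n_runs
  grids <- vector("list", n_runs)
  fates <- vector("list", n_runs)
  rows <- list()
  for (k in seq_len(n_runs) - 1) {
    run_seed <- scn$seed * 64 + k  # disjoint substreams under one master seed
    res <- simulate_run(setup$scene, setup$detectors,
                        origin = scn$beam$origin, direction = dirs[k + 1, ],
                        fwhm_um = scn$beam$fwhm_um,
                        n_photons = scn$beam$n_photons, seed = run_seed,
                        materials = materials,
                        max_scatters = scn$max_scatters, run_index = k,
                        record = record)
    if (!conservation_ok(res))
      stop("photon conservation ledger violated in run ", k)
    grids[[k + 1]] <- res$grids
    fates[[k + 1]] <- res$fates
    for (g in res$grids) {
      rows[[length(rows) + 1L]] <- data.frame(
        run = k, detector = g$detector$name,
        n_crossings = g$n_crossings,
        fraction_pct = detection_fraction(g))
    }
  }
  summary <- do.call(rbind, rows)
  out <- structure(list(scenario = scn, scene = setup$scene,
                        detectors = setup$detectors, directions = dirs,
                        grids = grids, fates = fates, summary = summary),
                   class = "scenario_result")
  if (!is.null(out_dir)) write_scenario_result(out, out_dir)
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s: %d runs x %d detectors, %s photons/run\n",
              x$scenario$name, length(x$grids), length(x$detectors),
              format(x$scenario$beam$n_photons, big.mark = ",")))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# grids + summary CSV + manifest to disk
write_scenario_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scn <- res$scenario
  for (k in seq_along(res$grids)) {
    for (g in res$grids[[k]]) {
      fn <- file.path(out_dir, sprintf("%s_run%d_%s.txt", scn$name, k - 1,
                                       g$detector$name))
      write_detector_grid(g, fn, seed = scn$seed * 64 + (k - 1))
    }
  }
  utils::write.csv(res$summary, file.path(out_dir, paste0(scn$name, "_summary.csv")),
                   row.names = FALSE)
  cfg_path <- file.path(out_dir, paste0(scn$name, "_config.yml"))
  write_scenario_config(scn, cfg_path)
  manifest <- list(
    scenario = scn$name,
    config_file = basename(cfg_path),
    config_md5 = unname(tools::md5sum(cfg_path)),
    master_seed = scn$seed,
    run_seeds = scn$seed * 64 + seq_along(res$grids) - 1,
    package_version = as.character(utils::packageVersion("drusim")),
    fates = lapply(res$fates, as.list))
  yaml::write_yaml(manifest, file.path(out_dir, paste0(scn$name, "_manifest.yml")))
  invisible(out_dir)
}

#' Serialize / restore a scenario config
#'
#' Scenario round-trips losslessly through a structured YAML file (units
#' are explicit in the field names: mm, um, eV).
#'
#' @param scn A [scenario()].
#' @param path YAML file path.
#' @return `write_scenario_config` returns `path` invisibly;
#'   `read_scenario_config` the reconstructed [scenario()].
#' @export
write_scenario_config <- function(scn, path) {
  druse <- NULL
  if (!is.null(scn$druse)) {
    druse <- list(position = scn$druse$position)
    if (!is.null(scn$druse$catalog_id)) {
      druse$shape <- scn$druse$catalog_id
    } else {
      druse$shape_kind <- scn$druse$shape$kind
      druse$shape_params_mm <- as.numeric(scn$druse$shape$params)
    }
  }
  cfg <- list(
    name = scn$name,
    druse = druse,
    geometry_mm = scn$geometry,
    beam = list(energy_eV = scn$beam$energy_ev,
                fwhm_um = scn$beam$fwhm_um,
                origin_mm = scn$beam$origin,
                axis_direction = scn$beam$axis_direction,
                n_photons = scn$beam$n_photons,
                scan_step_um = scn$beam$scan_step_um,
                n_runs = scn$beam$n_runs),
    detectors = scn$detectors,
    seed = scn$seed,
    max_scatters = scn$max_scatters)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  b <- cfg$beam
  beam <- beam_spec(energy_ev = b$energy_eV, fwhm_um = b$fwhm_um,
                    origin = unlist(b$origin_mm),
                    axis_direction = unlist(b$axis_direction),
                    n_photons = b$n_photons, scan_step_um = b$scan_step_um,
                    n_runs = b$n_runs)
  druse <- NULL
  if (!is.null(cfg$druse)) {
    druse <- list(position = cfg$druse$position)
    druse$shape <- if (!is.null(cfg$druse$shape)) {
      cfg$druse$shape
    } else {
      new_shape(cfg$druse$shape_kind, unlist(cfg$druse$shape_params_mm))
    }
  }
  geometry <- cfg$geometry_mm
  if (is.null(geometry)) geometry <- list()
  geometry <- lapply(geometry, unlist)
  dets <- cfg$detectors
  if (length(dets) > 1) dets <- unlist(dets)
  scenario(cfg$name, druse = druse, geometry = geometry, beam = beam,
           detectors = dets, seed = cfg$seed,
           max_scatters = cfg$max_scatters)
}

#' Generate a synthetic detector-grid fixture
#'
#' Builds a grid with a controllable, approximately Gaussian beam spot:
#' expected counts are
#' `background + amplitude * G(x; cx, sigma) * G_skew(y; cy, sigma, skew)`
#' where the y-factor uses `sigma * skew` on the right flank (`y > cy`)
#' and `sigma` on the left, so `skew = 1` is a symmetric spot and
#' `skew > 1` fattens the right flank. Counts are Poisson-sampled
#' (deterministically under `seed`) unless `poisson = FALSE`, which
#' rounds the expected counts instead.
#'
#' @param amplitude Peak expected count.
#' @param sigma Spot width, mm.
#' @param center Spot center `(x, y)`, mm.
#' @param skew Right-flank width multiplier (> 0).
#' @param background Uniform expected background count.
#' @param seed Integer seed for the Poisson noise.
#' @param poisson Apply Poisson noise (default) or return the rounded
#'   expectation.
#' @param detector The [detector()] whose geometry the fixture mimics
#'   (default: an 8.5 mm outside station at z = 30).
#' @param run_index Run label for the grid.
#' @return A [detector_grid()]; `n_generated` is left `NA` (a fixture has
#'   no generating beam).
#' @export
generate_fixture <- function(amplitude, sigma, center = c(0, 0), skew = 1,
                             background = 0, seed = 1, poisson = TRUE,
                             detector = NULL, run_index = NA_integer_) {
  stopifnot(sigma > 0, skew > 0, amplitude >= 0, background >= 0)
  if (is.null(detector))
    detector <- detector("FIX", 30, 8.5, filter = "+z")
  d <- detector
  wx <- d$side_lengths[1] / d$bins
  wy <- d$side_lengths[2] / d$bins
  x <- -d$side_lengths[1] / 2 + (seq_len(d$bins) - 0.5) * wx
  y <- -d$side_lengths[2] / 2 + (seq_len(d$bins) - 0.5) * wy
  gx <- exp(-(x - center[1])^2 / (2 * sigma^2))
  sig_y <- ifelse(y > center[2], sigma * skew, sigma)
  gy <- exp(-(y - center[2])^2 / (2 * sig_y^2))
  lambda <- background + amplitude * outer(gx, gy)
  counts <- if (poisson) {
    set.seed(seed)
    matrix(stats::rpois(length(lambda), lambda), nrow = d$bins)
  } else {
    round(lambda)
  }
  storage.mode(counts) <- "integer"
  detector_grid(d, counts, run_index = run_index)
}
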