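#' Virtual detector plane
#'
#' A transparent finite plane normal to the optical (z) axis that bins
#' photon crossings into a square grid. Detectors tally but never
#' interact: enabling or disabling them changes no photon fate.
#'
#' @param name Detector identifier.
#' @param z Axial position of the plane, mm.
#' @param side_lengths Sensitive extent (x, y), mm; a scalar is recycled.
#' @param bins Grid resolution per axis (default 200).
#' @param center_xy Lateral center of the sensitive area, mm.
#' @param filter Crossing-direction filter: `"-z"` tallies photons moving
#'   toward negative z (incoming beam), `"+z"` photons moving toward
#'   positive z (reflected beam), `"both"` tallies all crossings.
#' @return An object of class `"detector"`.
#' @export
detector <- function(name, z, side_lengths, bins = 200, center_xy = c(0, 0),
                     filter = c("+z", "-z", "both")) {
  filter <- match.arg(filter)
  side_lengths <- rep_len(as.numeric(side_lengths), 2)
  stopifnot(all(side_lengths > 0), bins >= 1)
  structure(list(name = name, z = z, side_lengths = side_lengths,
                 bins = as.integer(bins), center_xy = as.numeric(center_xy),
                 filter = filter),
            class = "detector")
}

#' Default detector stations
#'
#' The ten tally planes of the study, placed relative to the scene's
#' corneal apex (z = 0) and the inner ILM surface on the optical axis:
#' * `DA` (2 x 2 mm, 1.74 mm in front of the cornea) and `DB`
#'   (0.28 x 0.28 mm, 106 um in front of the retina) record the incident
#'   (-z) beam;
#' * `D1` (2 x 2 mm, 556 um in front of the retina, inside the eye) and
#'   the outside stations `D2`..`D8` (8.5 x 8.5 mm at 1, 2.5, 2.7, 3, 5,
#'   7 and 9 cm from the cornea) record the reflected (+z) beam.
#'
#' All grids are 200 x 200.
#'
#' @param sc A [scene()] from [build_eye()] (its landmarks set the retinal
#'   reference plane).
#' @return Named list of [detector()] objects.
#' @export
default_detectors <- function(sc) {
  zr <- sc$meta$landmarks$z_retina_axis
  if (is.null(zr)) stop("scene has no retinal landmark; build it with build_eye()")
  dets <- list(
    detector("DA", 1.74, 2.0, filter = "-z"),
    detector("DB", zr + 0.106, 0.28, filter = "-z"),
    detector("D1", zr + 0.556, 2.0, filter = "+z"),
    detector("D2", 10, 8.5, filter = "+z"),
    detector("D3", 25, 8.5, filter = "+z"),
    detector("D4", 27, 8.5, filter = "+z"),
    detector("D5", 30, 8.5, filter = "+z"),
    detector("D6", 50, 8.5, filter = "+z"),
    detector("D7", 70, 8.5, filter = "+z"),
    detector("D8", 90, 8.5, filter = "+z")
  )
  names(dets) <- vapply(dets, `[[`, character(1), "name")
  dets
}

#' Detector grid
#'
#' Tally result of one detector in one run: an integer count matrix
#' (`counts[ix, iy]`, x-bin by y-bin) whose sum equals the number of
#' in-extent crossings.
#'
#' @param det A [detector()].
#' @param counts Integer bins x bins matrix (default all zero).
#' @param run_index Scan run the grid belongs to (0-based), or `NA`.
#' @param n_generated Photons generated in the run (for fractions).
#' @return An object of class `"detector_grid"`.
#' @export
detector_grid <- function(det, counts = NULL, run_index = NA_integer_,
                          n_generated = NA_real_) {
  stopifnot(inherits(det, "detector"))
  if (is.null(counts)) counts <- matrix(0L, det$bins, det$bins)
  stopifnot(nrow(counts) == det$bins, ncol(counts) == det$bins,
            all(counts >= 0))
  structure(list(detector = det, counts = counts,
                 n_crossings = sum(as.numeric(counts)),
                 run_index = run_index, n_generated = n_generated),
            class = "detector_grid")
}

#' @export
print.detector_grid <- function(x, ...) {
  cat(sprintf("<detector_grid> %s run=%s: %d x %d bins, %s crossings\n",
              x$detector$name, x$run_index, nrow(x$counts), ncol(x$counts),
              format(x$n_crossings, big.mark = ",")))
  invisible(x)
}

#' Bin index of a plane coordinate
#'
#' Half-open binning `[low, high)` with the last bin closed at the top
#' edge; bin 1 starts at `-side/2`. Returns `NA` outside the extent.
#'
#' @param coord Plane coordinate relative to the detector center, mm.
#' @param side Side length of the sensitive area, mm.
#' @param bins Number of bins.
#' @return 1-based bin indices (`NA` = outside).
#' @export
grid_bin_index <- function(coord, side, bins) {
  half <- side / 2
  ix <- floor((coord / side + 0.5) * bins) + 1
  ix[ix == bins + 1 & coord <= half] <- bins  # top edge belongs to last bin
  ix[coord < -half | coord > half] <- NA_integer_
  as.integer(ix)
}

#' Record a crossing on a grid
#'
#' Increments exactly one bin for a crossing point given in plane
#' coordinates; a point outside the finite extent is a no-op.
#'
#' @param grid A [detector_grid()].
#' @param point Crossing point `(x, y)` in plane coordinates, mm.
#' @return The updated grid.
#' @export
record_crossing <- function(grid, point) {
  stopifnot(inherits(grid, "detector_grid"), length(point) == 2)
  d <- grid$detector
  p <- as.numeric(point) - d$center_xy
  ix <- grid_bin_index(p[1], d$side_lengths[1], d$bins)
  iy <- grid_bin_index(p[2], d$side_lengths[2], d$bins)
  if (!is.na(ix) && !is.na(iy)) {
    grid$counts[ix, iy] <- grid$counts[ix, iy] + 1L
    grid$n_crossings <- grid$n_crossings + 1
  }
  grid
}

#' Detected fraction of the generated beam
#'
#' @param grid A [detector_grid()].
#' @param n_generated Photons generated; defaults to the grid's own
#'   record.
#' @return Percentage `100 * n_crossings / n_generated`.
#' @export
detection_fraction <- function(grid, n_generated = grid$n_generated) {
  stopifnot(inherits(grid, "detector_grid"), n_generated > 0)
  100 * grid$n_crossings / n_generated
}

#' Write / read a detector grid as plain text
#'
#' Grid files carry `#`-prefixed header lines (detector geometry, run,
#' seed, photons generated) followed by the bins x bins integer matrix,
#' one y-row per line ordered by increasing x within the line. The
#' round-trip is bit-exact.
#'
#' @param grid A [detector_grid()].
#' @param path Output file.
#' @param seed Seed recorded in the header (optional).
#' @return `write_detector_grid` returns `path` invisibly;
#'   `read_detector_grid` returns the reconstructed [detector_grid()].
#' @export
write_detector_grid <- function(grid, path, seed = NA) {
  d <- grid$detector
  hdr <- c(
    sprintf("# detector: %s", d$name),
    sprintf("# z_mm: %.17g", d$z),
    sprintf("# side_lengths_mm: %.17g %.17g", d$side_lengths[1], d$side_lengths[2]),
    sprintf("# center_xy_mm: %.17g %.17g", d$center_xy[1], d$center_xy[2]),
    sprintf("# bins: %d", d$bins),
    sprintf("# filter: %s", d$filter),
    sprintf("# run_index: %s", grid$run_index),
    sprintf("# n_generated: %s", format(grid$n_generated, scientific = FALSE)),
    sprintf("# seed: %s", seed)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  # one line per y-row: counts[, iy] across x
  utils::write.table(t(grid$counts), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_detector_grid
#' @export
read_detector_grid <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  hdr <- list()
  for (l in hdr_lines) {
    kv <- sub("^#\\s*", "", l)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:\\s*", "", kv))
    hdr[[key]] <- val
  }
  mat <- utils::read.table(text = lines[!grepl("^#", lines)])
  counts <- t(as.matrix(mat))
  dimnames(counts) <- NULL
  storage.mode(counts) <- "integer"
  side <- as.numeric(strsplit(hdr$side_lengths_mm, "\\s+")[[1]])
  ctr <- as.numeric(strsplit(hdr$center_xy_mm, "\\s+")[[1]])
  det <- detector(hdr$detector, as.numeric(hdr$z_mm), side,
                  bins = as.integer(hdr$bins), center_xy = ctr,
                  filter = hdr$filter)
  detector_grid(det, counts,
                run_index = suppressWarnings(as.integer(hdr$run_index)),
                n_generated = suppressWarnings(as.numeric(hdr$n_generated)))
}
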