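#' Mean free path from an attenuation coefficient
#'
#' Converts an absorption or reduced-scattering coefficient into the
#' corresponding interaction mean free path. Coefficients may be given in
#' mm^-1 (the dominant unit of the bundled material table) or cm^-1 (the
#' unit in which the druse coefficients are tabulated); all lengths inside
#' the package are millimetres.
#'
#' @param mu Attenuation coefficient, strictly positive.
#' @param unit Unit of `mu`: `"mm^-1"` (default) or `"cm^-1"`.
#' @return Mean free path in mm (`1/mu` after unit conversion). No rounding
#'   is applied; round only at presentation time.
#' @examples
#' mfp_from_coefficient(0.25)          # 4 mm (sclera absorption)
#' mfp_from_coefficient(12.6, "cm^-1") # 0.7937 mm (druse absorption)
#' @export
mfp_from_coefficient <- function(mu, unit = c("mm^-1", "cm^-1")) {
  unit <- match.arg(unit)
  if (!is.numeric(mu) || any(!is.finite(mu)) || any(mu <= 0)) {
    stop("'mu' must be a positive, finite attenuation coefficient")
  }
  mu_mm <- if (unit == "cm^-1") mu / 10 else mu
  1 / mu_mm
}

#' Photon wavelength from energy
#'
#' @param energy_ev Photon energy in eV, strictly positive.
#' @return Wavelength in nm, `1239.842 / energy_ev` (hc = 1239.842 eV nm).
#' @examples
#' wavelength_from_energy(2) # 619.921 nm, i.e. orange light (~620 nm)
#' @export
wavelength_from_energy <- function(energy_ev) {
  if (!is.numeric(energy_ev) || any(!is.finite(energy_ev)) || any(energy_ev <= 0)) {
    stop("'energy_ev' must be positive and finite")
  }
  1239.842 / energy_ev
}

#' Optical properties of one material
#'
#' A material is fully described by its optical constants at the single
#' operating wavelength of the simulation (~620 nm): an absorption
#' coefficient `mu_a`, a reduced scattering coefficient `mu_s_reduced`
#' (both mm^-1), a refractive index `rindex`, and the derived mean free
#' paths `abslength` and `rayleigh` (mm) that drive transport. Any field
#' may be absent (`NA`):
#' * absent `abslength`/`rayleigh` means the corresponding process does not
#'   occur in that material;
#' * an absent `rindex` makes the material a terminal absorber at its
#'   boundary (every photon reaching it is absorbed on the surface, as for
#'   the iris).
#'
#' If a mean free path is not supplied explicitly it is derived as the
#' reciprocal of the corresponding coefficient.
#'
#' @param name Material identifier.
#' @param mu_a Absorption coefficient, mm^-1 (optional).
#' @param mu_s_reduced Reduced scattering coefficient mu_s', mm^-1 (optional).
#' @param rindex Refractive index >= 1 (optional).
#' @param abslength Bulk-absorption mean free path, mm (optional override).
#' @param rayleigh Scattering mean free path, mm (optional override).
#' @param g Scattering anisotropy in `[-1, 1]`. Documentation only: the
#'   transport kernel uses `mu_s_reduced` with a fixed symmetric phase
#'   function, so `g` never enters the simulation.
#' @return An object of class `"optical_properties"`.
#' @export
optical_properties <- function(name, mu_a = NA_real_, mu_s_reduced = NA_real_,
                               rindex = NA_real_, abslength = NA_real_,
                               rayleigh = NA_real_, g = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  num1 <- function(x, what) {
    x <- as.numeric(x)
    if (length(x) != 1L) stop("'", what, "' must be a single value")
    x
  }
  mu_a <- num1(mu_a, "mu_a"); mu_s_reduced <- num1(mu_s_reduced, "mu_s_reduced")
  rindex <- num1(rindex, "rindex")
  abslength <- num1(abslength, "abslength"); rayleigh <- num1(rayleigh, "rayleigh")
  g <- num1(g, "g")
  if (!is.na(mu_a) && mu_a <= 0) stop("'mu_a' must be > 0 when present")
  if (!is.na(mu_s_reduced) && mu_s_reduced <= 0) stop("'mu_s_reduced' must be > 0 when present")
  if (!is.na(rindex) && rindex < 1) stop("'rindex' must be >= 1 when present")
  if (!is.na(g) && (g < -1 || g > 1)) stop("'g' must lie in [-1, 1]")
  if (is.na(abslength) && !is.na(mu_a)) abslength <- 1 / mu_a
  if (is.na(rayleigh) && !is.na(mu_s_reduced)) rayleigh <- 1 / mu_s_reduced
  if (!is.na(abslength) && abslength <= 0) stop("'abslength' must be > 0 when present")
  if (!is.na(rayleigh) && rayleigh <= 0) stop("'rayleigh' must be > 0 when present")
  structure(
    list(name = name, mu_a = mu_a, mu_s_reduced = mu_s_reduced, g = g,
         rindex = rindex, abslength = abslength, rayleigh = rayleigh),
    class = "optical_properties"
  )
}

#' @export
print.optical_properties <- function(x, ...) {
  fmt <- function(v, u) if (is.na(v)) "-" else paste(format(v, digits = 6), u)
  cat(sprintf("<optical_properties> %s\n", x$name))
  cat("  mu_a:      ", fmt(x$mu_a, "mm^-1"), "\n")
  cat("  mu_s':     ", fmt(x$mu_s_reduced, "mm^-1"), "\n")
  cat("  rindex:    ", fmt(x$rindex, ""), "\n")
  cat("  abslength: ", fmt(x$abslength, "mm"), "\n")
  cat("  rayleigh:  ", fmt(x$rayleigh, "mm"), "\n")
  invisible(x)
}

#' Material table
#'
#' A named collection of [optical_properties()] objects, indexed by
#' material identifier.
#'
#' @param materials A list of `optical_properties` objects.
#' @return An object of class `"material_table"`.
#' @seealso [default_material_table()]
#' @export
material_table <- function(materials) {
  stopifnot(is.list(materials))
  ok <- vapply(materials, inherits, logical(1), "optical_properties")
  if (!all(ok)) stop("all elements must be 'optical_properties' objects")
  names(materials) <- vapply(materials, `[[`, character(1), "name")
  if (anyDuplicated(names(materials))) stop("duplicate material names")
  structure(list(materials = materials), class = "material_table")
}

#' @export
print.material_table <- function(x, ...) {
  cat(sprintf("<material_table> %d materials: %s\n",
              length(x$materials), paste(names(x$materials), collapse = ", ")))
  invisible(x)
}

#' Look up a material
#'
#' @param table A [material_table()].
#' @param name Material identifier.
#' @return The `optical_properties` entry.
#' @export
material <- function(table, name) {
  stopifnot(inherits(table, "material_table"))
  m <- table$materials[[name]]
  if (is.null(m)) stop("unknown material: ", name)
  m
}

#' Bundled material table of the simulated eye tissues
#'
#' Optical properties of the twelve simulated media at the 2 eV (~620 nm)
#' operating point: air, sclera, cornea, aqueous humor, iris, crystalline
#' lens, vitreous humor, the three retinal layers (ILM, NR, RPE), druse
#' material, and choroid. Absorption and reduced-scattering coefficients
#' follow measured bovine-eye tissue optics; druse coefficients follow a
#' 50% lipid / 50% protein composition (tabulated in cm^-1 and converted at
#' load). The tabulated `abslength`/`rayleigh` values are the mean free
#' paths actually used by transport; they equal the reciprocal coefficients
#' up to the precision of the source table.
#'
#' Two deliberate features of the table:
#' * the iris has no optical constants at all, which makes it a fully
#'   absorbing boundary (photons reaching it are terminated there);
#' * all retinal layers, the druse and the vitreous share `rindex` 1.337,
#'   cancelling Fresnel reflections at intra-retinal surfaces so that only
#'   scattering and absorption distinguish them.
#'
#' @return A [material_table()] with entries `Air`, `Sclera`, `Cornea`,
#'   `Aqueous humor`, `Iris`, `Crystalline lens`, `Vitreous humor`, `ILM`,
#'   `NR`, `RPE`, `Druse`, `Choroid`.
#' @examples
#' tab <- default_material_table()
#' material(tab, "Druse")$rayleigh   # 0.0243 mm
#' material(tab, "Iris")$rindex      # NA: terminal absorber
#' @export
default_material_table <- function() {
  material_table(list(
    optical_properties("Air", rindex = 1.000),
    optical_properties("Sclera", mu_a = 0.25, mu_s_reduced = 8.00,
                       rindex = 1.47, abslength = 4.0, rayleigh = 0.1250),
    optical_properties("Cornea", rindex = 1.376),
    optical_properties("Aqueous humor", rindex = 1.336),
    optical_properties("Iris"),
    optical_properties("Crystalline lens", rindex = 1.405),
    optical_properties("Vitreous humor", rindex = 1.337),
    optical_properties("ILM", mu_a = 0.25, mu_s_reduced = 0.75,
                       rindex = 1.337, abslength = 4.0, rayleigh = 1.333),
    optical_properties("NR", mu_a = 0.25, mu_s_reduced = 0.75,
                       rindex = 1.337, abslength = 4.0, rayleigh = 1.333),
    optical_properties("RPE", mu_a = 90.00, mu_s_reduced = 19.20,
                       rindex = 1.337, abslength = 0.0111, rayleigh = 0.0521),
    # druse coefficients are tabulated in cm^-1; convert at load
    optical_properties("Druse",
                       mu_a = 12.6 / 10, mu_s_reduced = 412 / 10,
                       rindex = 1.337, abslength = 0.7936, rayleigh = 0.0243),
    optical_properties("Choroid", mu_a = 8.00, mu_s_reduced = 3.60,
                       rindex = 1.337, abslength = 0.1250, rayleigh = 0.2778)
  ))
}

#' Read a material table from a YAML config
#'
#' One record per material. Recognised keys per record: `name` (required),
#' `mu_a`, `mu_s_reduced` (optionally as strings with an explicit unit,
#' e.g. `"12.6 cm^-1"`), `rindex`, `g`, and explicit `abslength` /
#' `rayleigh` overrides in mm. Records override or extend the bundled
#' defaults unless `base = NULL`.
#'
#' @param path Path to a YAML file with a top-level `materials:` list.
#' @param base Table to override (default [default_material_table()]);
#'   `NULL` starts from an empty table.
#' @return A [material_table()].
#' @export
read_material_config <- function(path, base = default_material_table()) {
  cfg <- yaml::read_yaml(path)
  recs <- cfg$materials
  if (is.null(recs)) stop("config has no 'materials' section: ", path)
  mats <- if (is.null(base)) list() else base$materials
  for (r in recs) {
    if (is.null(r$name)) stop("material record without 'name'")
    coef <- function(v) {
      if (is.null(v)) return(NA_real_)
      if (is.character(v)) {
        parts <- strsplit(trimws(v), "\\s+")[[1]]
        mu <- as.numeric(parts[1])
        unit <- if (length(parts) > 1) parts[2] else "mm^-1"
        if (!unit %in% c("mm^-1", "cm^-1")) stop("unknown unit: ", unit)
        return(if (unit == "cm^-1") mu / 10 else mu)
      }
      as.numeric(v)
    }
    opt <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
    mats[[r$name]] <- optical_properties(
      r$name, mu_a = coef(r$mu_a), mu_s_reduced = coef(r$mu_s_reduced),
      rindex = opt(r$rindex), abslength = opt(r$abslength),
      rayleigh = opt(r$rayleigh), g = opt(r$g)
    )
  }
  material_table(unname(mats))
}

#' Material table as a data frame
#'
#' @param x A [material_table()].
#' @param ... Unused.
#' @return A data frame with one row per material.
#' @export
as.data.frame.material_table <- function(x, ...) {
  do.call(rbind, lapply(x$materials, function(m) {
    data.frame(name = m$name, mu_a = m$mu_a, mu_s_reduced = m$mu_s_reduced,
               rindex = m$rindex, abslength = m$abslength,
               rayleigh = m$rayleigh, row.names = NULL)
  }))
}
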