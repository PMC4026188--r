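#' Sample interaction free paths
#'
#' Exponential free-path sampling, `-mfp * log(u)` with `u ~ U(0,1)`. An
#' absent (`NA`) mean free path means the corresponding process does not
#' occur in the material: the returned path is infinite.
#'
#' @param n Number of draws.
#' @param mfp Mean free path, mm (> 0), or `NA` for "process absent".
#' @param seed Integer seed.
#' @return Numeric vector of path lengths, mm.
#' @export
sample_free_path <- function(n, mfp, seed = 1) {
  if (is.na(mfp)) return(rep(Inf, n))
  if (mfp <= 0) stop("'mfp' must be > 0")
  cpp_sample_free_path(as.integer(n), mfp, as.double(seed))
}

#' Phase-function density of the scattering polar angle
#'
#' Normalized density of `mu = cos(theta)` for the Rayleigh-type
#' `(1 + cos^2 theta)` phase function: `p(mu) = 3 (1 + mu^2) / 8` on
#' `[-1, 1]`. Symmetric, so the mean scattering cosine is zero; the
#' anisotropy of real tissue is carried entirely by the reduced
#' scattering coefficient, not by the phase shape.
#'
#' @param mu Cosine(s) of the scattering angle.
#' @return Density values.
#' @export
phase_function_density <- function(mu) {
  out <- 3 * (1 + mu^2) / 8
  out[mu < -1 | mu > 1] <- 0
  out
}

#' Sample scattering-angle cosines
#'
#' Draws `cos(theta)` from the `(1 + cos^2 theta)` phase function by exact
#' inversion of the cubic CDF (`mu^3 + 3 mu + 4 - 8u = 0`). The azimuth of
#' a scatter is uniform and sampled separately inside the kernel.
#'
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param u Optional explicit uniforms in (0,1); overrides `n`/`seed` and
#'   applies the inverse CDF deterministically.
#' @return Cosines in `[-1, 1]`.
#' @export
sample_scatter_cosine <- function(n, seed = 1, u = NULL) {
  if (!is.null(u)) {
    stopifnot(all(u >= 0 & u <= 1))
    return(cpp_phase_cosine_from_u(as.numeric(u)))
  }
  cpp_sample_scatter_cosine(as.integer(n), as.double(seed))
}

#' Unpolarized Fresnel reflectance
#'
#' Average of the s- and p-polarized Fresnel reflectances at a planar
#' refractive-index step. Returns 1 beyond the critical angle (total
#' internal reflection) and exactly 0 for matched indices.
#'
#' @param theta_i Angle of incidence from the surface normal, rad.
#' @param n1,n2 Refractive indices of the incident and transmitting media.
#' @return Reflection probabilities in `[0, 1]`.
#' @examples
#' fresnel_reflectance(0, 1, 1.5)  # ((1-1.5)/(1+1.5))^2 = 0.04
#' @export
fresnel_reflectance <- function(theta_i, n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  cpp_fresnel_reflectance(cos(theta_i), n1, n2)
}

#' Boundary interaction of a photon
#'
#' Resolves one photon-surface event: if the entered material has no
#' refractive index the photon is absorbed at the boundary (the iris
#' rule); otherwise it is specularly reflected with probability equal to
#' the unpolarized Fresnel reflectance and refracted by Snell's law
#' otherwise, with total internal reflection beyond the critical angle.
#'
#' @param direction Incoming unit direction.
#' @param normal Unit surface normal oriented against `direction`
#'   (`dot(normal, direction) < 0`).
#' @param n1 Refractive index on the incident side (>= 1).
#' @param n2 Refractive index on the far side, or `NA` if the entered
#'   material has none (terminal absorber).
#' @param u Uniform random number deciding the reflect/refract split;
#'   supply explicitly for deterministic tests, or leave default to draw
#'   from the R session RNG.
#' @return List with `event` (`"reflected"`, `"refracted"`, or
#'   `"absorbed_at_boundary"`), the outgoing `direction`, and (when
#'   applicable) the `reflectance` used for the split.
#' @export
boundary_event <- function(direction, normal, n1, n2 = NA_real_,
                           u = stats::runif(1)) {
  stopifnot(n1 >= 1)
  cpp_boundary_interaction(as.numeric(direction), as.numeric(normal),
                           n1, if (is.na(n2)) 1.0 else n2, is.na(n2),
                           u)
}

#' Propagate a single photon
#'
#' Full analog transport of one photon through a scene: per step the
#' absorption free path, the scattering free path and the distance to the
#' nearest region boundary compete; the shortest wins. Terminal events are
#' bulk absorption, boundary absorption (material without refractive
#' index), world exit, or the scatter cap.
#'
#' @param sc A [scene()].
#' @param position,direction Initial photon state (inside the world).
#' @param materials A [material_table()].
#' @param seed Integer seed.
#' @param max_scatters Scatter cap (default 1e5).
#' @param detectors Optional detector list; crossings are tallied but do
#'   not affect transport.
#' @return One-row data frame: `fate`, `path_mm`, `n_scatters`, final
#'   position `x,y,z` and direction `dx,dy,dz`.
#' @export
propagate_photon <- function(sc, position, direction,
                             materials = default_material_table(),
                             seed = 1, max_scatters = 1e5,
                             detectors = list()) {
  res <- cpp_simulate(scene_for_kernel(sc, materials),
                      materials_for_kernel(materials),
                      lapply(detectors, unclass),
                      as.numeric(position),
                      as.numeric(direction), 0.0, 1L, as.double(seed),
                      as.integer(max_scatters), 1L)
  res$records
}
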