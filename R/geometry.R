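#' Shape constructors
#'
#' Axis-aligned solid shapes used to build scene volumes, mirroring the
#' solids of general-purpose particle-transport toolkits: boxes, full
#' spheres, sphere sections (radial shell with polar-angle limits measured
#' from the local +z axis), ellipsoids, and cylindrical tubes (annular
#' discs, used for the iris diaphragm). All dimensions in mm, angles in
#' radians.
#'
#' @param hx,hy,hz Half-side lengths of a box / half-height of a tube.
#' @param radius Sphere radius.
#' @param rmin,rmax Inner/outer radii of a sphere section or tube.
#' @param theta_min,theta_max Polar-angle limits of a sphere section,
#'   measured from the shape's +z axis; `c(0, pi)` gives a full shell.
#' @param a,b,c Ellipsoid semi-axes along x, y, z.
#' @return An object of class `"shape"` with fields `kind` and `params`.
#' @name shapes
NULL

new_shape <- function(kind, params) {
  if (any(!is.finite(params))) stop("shape parameters must be finite")
  structure(list(kind = kind, params = as.numeric(params)), class = "shape")
}

#' @rdname shapes
#' @export
shape_box <- function(hx, hy, hz) {
  if (min(hx, hy, hz) <= 0) stop("box half-sides must be > 0")
  new_shape("box", c(hx, hy, hz))
}

#' @rdname shapes
#' @export
shape_full_sphere <- function(radius) {
  if (radius <= 0) stop("sphere radius must be > 0")
  new_shape("full-sphere", radius)
}

#' @rdname shapes
#' @export
shape_sphere_section <- function(rmin, rmax, theta_min = 0, theta_max = pi) {
  if (rmax <= 0 || rmin < 0 || rmin >= rmax) stop("need 0 <= rmin < rmax")
  if (theta_min < 0 || theta_max > pi + 1e-12 || theta_min >= theta_max)
    stop("need 0 <= theta_min < theta_max <= pi")
  new_shape("sphere-section", c(rmin, rmax, theta_min, theta_max))
}

#' @rdname shapes
#' @export
shape_ellipsoid <- function(a, b, c) {
  if (min(a, b, c) <= 0) stop("ellipsoid semi-axes must be > 0")
  new_shape("ellipsoid", c(a, b, c))
}

#' @rdname shapes
#' @export
shape_tube <- function(rmin, rmax, hz) {
  if (rmax <= 0 || rmin < 0 || rmin >= rmax || hz <= 0)
    stop("need 0 <= rmin < rmax and hz > 0")
  new_shape("tube", c(rmin, rmax, hz))
}

#' Placed volume
#'
#' A shape placed in the world frame (translation only; all shapes are
#' axis-aligned), filled with a named material, and optionally tied to a
#' containing parent volume for documentation/validation.
#'
#' @param name Volume identifier (unique within a scene).
#' @param shape A [shapes] object.
#' @param center Translation of the shape's local origin, mm.
#' @param material Material identifier (resolved against a
#'   [material_table()] at simulation time).
#' @param parent Name of the containing volume, or `NA` for the world.
#' @return An object of class `"volume"`.
#' @export
volume <- function(name, shape, center, material, parent = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L, inherits(shape, "shape"),
            length(center) == 3L, is.character(material))
  structure(list(name = name, kind = shape$kind, params = shape$params,
                 center = as.numeric(center), material = material,
                 parent = parent),
            class = "volume")
}

#' Assemble a scene
#'
#' A scene is a priority-ordered list of volumes; the first volume must be
#' the world box. Point location resolves to the *highest-priority* (i.e.
#' last-listed) volume containing a point, so later volumes carve earlier
#' ones. This containment-priority rule replaces explicit boolean solids:
#' a layer listed after the body it sits in simply claims its region.
#'
#' @param volumes List of [volume()] objects in ascending priority; the
#'   first must be a box named however you like (conventionally "World").
#' @param meta Optional named list of scene metadata (kept as-is).
#' @return An object of class `"scene"`.
#' @export
scene <- function(volumes, meta = list()) {
  stopifnot(is.list(volumes), length(volumes) >= 1L)
  ok <- vapply(volumes, inherits, logical(1), "volume")
  if (!all(ok)) stop("all elements must be 'volume' objects")
  nms <- vapply(volumes, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate volume names")
  if (volumes[[1]]$kind != "box") stop("the first volume must be the world box")
  structure(list(volumes = volumes, names = nms, meta = meta), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d volumes (ascending priority):\n", length(x$volumes)))
  for (v in x$volumes)
    cat(sprintf("  %-18s %-14s material=%s\n", v$name, v$kind, v$material))
  invisible(x)
}

# scene in the flat list form consumed by the compiled kernel
scene_for_kernel <- function(sc, materials) {
  stopifnot(inherits(sc, "scene"), inherits(materials, "material_table"))
  mat_names <- names(materials$materials)
  vols <- lapply(sc$volumes, function(v) {
    idx <- match(v$material, mat_names)
    if (is.na(idx)) stop("scene references unknown material: ", v$material)
    list(name = v$name, kind = v$kind, params = v$params, center = v$center,
         material_index = idx)
  })
  list(volumes = vols)
}

materials_for_kernel <- function(materials) {
  m <- materials$materials
  list(abslength = vapply(m, `[[`, numeric(1), "abslength"),
       rayleigh = vapply(m, `[[`, numeric(1), "rayleigh"),
       rindex = vapply(m, `[[`, numeric(1), "rindex"))
}

#' Locate points in a scene
#'
#' Returns, for each query point, the name of the highest-priority volume
#' containing it (the innermost-wins rule); points outside the world box
#' are reported as `NA` (the out-of-world signal).
#'
#' @param sc A [scene()].
#' @param points Numeric 3-vector or an n x 3 matrix of points, mm.
#' @param materials A [material_table()] naming the scene's materials.
#' @return Character vector of volume names (`NA` = outside the world).
#' @export
locate <- function(sc, points, materials = default_material_table()) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  stopifnot(ncol(points) == 3)
  idx <- cpp_locate(scene_for_kernel(sc, materials), points)
  out <- rep(NA_character_, length(idx))
  out[idx > 0] <- sc$names[idx[idx > 0]]
  out
}

#' First boundary intersection along a ray
#'
#' Walks a ray from a point strictly inside `current_volume` to the first
#' surface at which the located volume changes, and reports the distance,
#' the surface normal (oriented against the incoming direction), and the
#' volume entered (`NA` when the ray leaves the world).
#'
#' @param sc A [scene()].
#' @param origin Ray origin, mm (inside `current_volume`).
#' @param direction Unit direction vector (|d| = 1 within 1e-9).
#' @param current_volume Name of the volume containing `origin`; defaults
#'   to `locate()` of the origin.
#' @param materials A [material_table()].
#' @return List with `distance` (mm), `normal` (unit 3-vector with
#'   `dot(normal, direction) < 0`), and `entered` (volume name, `NA` for a
#'   world exit).
#' @export
first_intersection <- function(sc, origin, direction,
                               current_volume = NULL,
                               materials = default_material_table()) {
  direction <- as.numeric(direction)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9)
    stop("'direction' must be a unit vector")
  if (is.null(current_volume)) {
    current_volume <- locate(sc, origin, materials)
    if (is.na(current_volume)) stop("origin is outside the world")
  }
  cur <- match(current_volume, sc$names)
  if (is.na(cur)) stop("unknown volume: ", current_volume)
  res <- cpp_first_intersection(scene_for_kernel(sc, materials),
                                as.numeric(origin), direction, cur)
  if (!res$found) stop("no boundary found along ray (origin outside world?)")
  list(distance = res$distance, normal = res$normal,
       entered = if (res$entered > 0) sc$names[res$entered] else NA_character_)
}

# deterministic low-discrepancy interior points of a shape, sampled
# parametrically (works for arbitrarily thin shells; no RNG state touched)
sample_shape_points <- function(v, n = 64) {
  halton <- function(i, base) {
    f <- 1; r <- 0
    while (any(i > 0)) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }
  i <- seq_len(n)
  # map into (0.02, 0.98) to keep points strictly interior
  u1 <- 0.02 + 0.96 * halton(i, 2)
  u2 <- 0.02 + 0.96 * halton(i, 3)
  u3 <- 0.02 + 0.96 * halton(i, 5)
  sph <- function(r, th, ph) cbind(r * sin(th) * cos(ph),
                                   r * sin(th) * sin(ph),
                                   r * cos(th))
  pts <- switch(v$kind,
    "box" = cbind((2 * u1 - 1) * v$params[1], (2 * u2 - 1) * v$params[2],
                  (2 * u3 - 1) * v$params[3]),
    "full-sphere" = sph(v$params[1] * u1^(1 / 3), acos(1 - 2 * u2),
                        2 * pi * u3),
    "sphere-section" = {
      r <- v$params[1] + (v$params[2] - v$params[1]) * u1
      th <- v$params[3] + (v$params[4] - v$params[3]) * u2
      sph(r, th, 2 * pi * u3)
    },
    "ellipsoid" = sweep(sph(u1^(1 / 3), acos(1 - 2 * u2), 2 * pi * u3),
                        2, v$params[1:3], `*`),
    "tube" = {
      r <- v$params[1] + (v$params[2] - v$params[1]) * u1
      cbind(r * cos(2 * pi * u3), r * sin(2 * pi * u3),
            (2 * u2 - 1) * v$params[3])
    })
  sweep(pts, 2, v$center, `+`)
}

point_in_shape <- function(v, p) {
  switch(v$kind,
    "box" = all(abs(p) <= v$params[1:3]),
    "full-sphere" = sum(p^2) <= v$params[1]^2,
    "sphere-section" = {
      r <- sqrt(sum(p^2))
      if (r < v$params[1] || r > v$params[2]) return(FALSE)
      th <- if (r > 0) acos(max(-1, min(1, p[3] / r))) else 0
      th >= v$params[3] - 1e-12 && th <= v$params[4] + 1e-12
    },
    "ellipsoid" = sum((p / v$params[1:3])^2) <= 1,
    "tube" = {
      rho2 <- p[1]^2 + p[2]^2
      rho2 >= v$params[1]^2 && rho2 <= v$params[2]^2 && abs(p[3]) <= v$params[3]
    })
}

#' Validate a scene
#'
#' Samples deterministic interior points for every volume and checks that
#' (i) every sampled point of every volume lies inside the world box (no
#' volume escapes the world), and (ii) every volume owns at least one
#' sampled point under the innermost-wins rule (no volume is completely
#' buried by higher-priority volumes). Volumes carved by design (e.g. a
#' body whose posterior region is claimed by layer volumes) still own the
#' uncarved remainder, so a fully hidden volume indicates a construction
#' error.
#'
#' @param sc A [scene()].
#' @param materials A [material_table()].
#' @param n_points Interior sample points per volume.
#' @return Invisibly `TRUE`; errors naming the offending volume otherwise.
#' @export
validate_scene <- function(sc, materials = default_material_table(),
                           n_points = 64) {
  ker <- scene_for_kernel(sc, materials)
  for (i in seq_along(sc$volumes)) {
    v <- sc$volumes[[i]]
    pts <- sample_shape_points(v, n_points)
    if (nrow(pts) == 0) stop("scene-validation error: volume '", v$name,
                             "' produced no interior points")
    idx <- cpp_locate(ker, pts)
    if (any(idx == 0) && i > 1)
      stop("scene-validation error: volume '", v$name,
           "' extends outside the world box")
    if (!any(idx == i))
      stop("scene-validation error: volume '", v$name,
           "' is completely hidden by higher-priority volumes")
  }
  invisible(TRUE)
}

#' Default eye-geometry parameters
#'
#' Global dimensions of the schematic eye (mm unless noted). The
#' crystalline lens (9 mm equatorial diameter, 3.7 mm thickness) follows
#' the relaxed-accommodation average; the remaining dimensions are a
#' standard schematic eye. The corneal apex sits at z = 0 and protrudes
#' `cornea_protrusion` beyond the scleral sphere (the anatomical corneal
#' bulge); the optical axis is z, and the beam travels in -z into the eye.
#'
#' @return Named list of geometry parameters; pass (partially) modified
#'   copies to [build_eye()].
#' @export
eye_defaults <- function() {
  list(
    world_half = c(55, 55, 70),       # world box half-sides
    world_center = c(0, 0, 30),
    sclera_outer_r = 12,              # globe radius
    sclera_thickness = 0.8,
    cornea_outer_r = 7.8,
    cornea_thickness = 0.55,
    cornea_protrusion = 0.3,          # corneal apex beyond the scleral sphere
    cornea_theta_deg = 49,            # angular half-extent of the corneal cap
    anterior_chamber_depth = 3.05,    # posterior cornea vertex to lens vertex
    aqueous_theta_deg = 53,           # angular extent of the aqueous region
    pupil_diameter = 4,
    iris_outer_r = 5.8,
    iris_thickness = 0.3,
    lens_equatorial_diameter = 9,
    lens_thickness = 3.7,
    ilm_thickness = 0.002,
    nr_thickness = 0.2,
    rpe_thickness = 0.01,
    choroid_thickness = 0.25,
    ora_serrata_deg = 60              # retinal-layer truncation from posterior pole
  )
}

# axial landmarks derived from the geometry parameters (corneal apex at z=0)
eye_landmarks <- function(g) {
  globe_z <- -(g$cornea_protrusion + g$sclera_outer_r)
  cornea_cz <- -g$cornea_outer_r             # corneal sphere center on axis
  r_sclera_in <- g$sclera_outer_r - g$sclera_thickness
  r_choroid_in <- r_sclera_in - g$choroid_thickness
  r_rpe_in <- r_choroid_in - g$rpe_thickness
  r_nr_in <- r_rpe_in - g$nr_thickness
  r_ilm_in <- r_nr_in - g$ilm_thickness
  lens_front_z <- -(g$cornea_thickness + g$anterior_chamber_depth)
  lens_cz <- lens_front_z - g$lens_thickness / 2
  iris_back_z <- lens_front_z + 0.15         # iris just in front of the lens
  list(globe_center = c(0, 0, globe_z),
       cornea_center = c(0, 0, cornea_cz),
       r_sclera_in = r_sclera_in, r_choroid_in = r_choroid_in,
       r_rpe_in = r_rpe_in, r_nr_in = r_nr_in, r_ilm_in = r_ilm_in,
       lens_center = c(0, 0, lens_cz),
       iris_center = c(0, 0, iris_back_z + g$iris_thickness / 2),
       z_retina_axis = globe_z - r_ilm_in)   # inner ILM surface on axis
}

# druse axial half-depth (extent along the optical axis) per catalog shape
druse_half_depth <- function(shape) {
  switch(shape$kind,
         "full-sphere" = shape$params[1],
         "ellipsoid" = shape$params[3],
         "box" = shape$params[3],
         stop("unsupported druse shape kind: ", shape$kind))
}

#' Build the schematic-eye scene
#'
#' Assembles the virtual eyeball: world box of air; scleral globe; vitreous
#' body; posterior retinal complex (choroid, RPE, NR, ILM as concentric
#' shells truncated at the ora serrata); corneal cap; aqueous region; iris
#' diaphragm with pupil aperture; biconvex lens (ellipsoid). Optional
#' drusen are added as the highest-priority volumes inside the retinal
#' complex, centered on the optical axis at the posterior pole.
#'
#' Druse placement depths (`position`):
#' * `"A"` — center at mid-NR depth (intermediate retinal depth);
#' * `"B"` — apex touching the ILM-NR boundary (superficial);
#' * `"C"` — base touching the NR-RPE boundary (deep);
#' * `"D"` — entirely beneath the RPE, on the choroid side (touching the
#'   RPE outer surface), modelling the earliest growth stage.
#'
#' @param geometry Parameter list from [eye_defaults()] (partial overrides
#'   allowed via `modifyList` semantics: pass only the fields to change).
#' @param drusen List of druse entries, each a list with `shape` (a
#'   [shapes] object: full sphere, ellipsoid, or box), `position` (`"A"`..
#'   `"D"`), and optional `offset` (lateral (x, y) offset in mm, default
#'   on-axis). `NULL` builds the druse-free eye.
#' @param validate Run [validate_scene()] on the result.
#' @param materials A [material_table()].
#' @return A [scene()] whose `meta` carries the geometry list and derived
#'   axial landmarks (`meta$landmarks`), used to place detectors and aim
#'   the scan.
#' @examples
#' eye <- build_eye()                      # druse-free, 10 eye structures
#' druse <- list(shape = shape_full_sphere(0.05), position = "A")
#' eye1 <- build_eye(drusen = list(druse)) # 100 um spherical druse, mid-NR
#' @export
build_eye <- function(geometry = list(), drusen = NULL, validate = TRUE,
                      materials = default_material_table()) {
  g <- utils::modifyList(eye_defaults(), geometry)
  if (any(vapply(g[c("sclera_outer_r", "cornea_outer_r", "cornea_thickness",
                     "pupil_diameter", "lens_equatorial_diameter",
                     "lens_thickness", "ilm_thickness", "nr_thickness",
                     "rpe_thickness", "choroid_thickness")],
                 function(x) x <= 0, logical(1))))
    stop("all eye dimensions must be > 0")
  lm <- eye_landmarks(g)
  deg <- pi / 180
  ora <- pi - g$ora_serrata_deg * deg  # shells span [ora, pi] about +z

  vols <- list(
    volume("World", shape_box(g$world_half[1], g$world_half[2], g$world_half[3]),
           g$world_center, "Air"),
    volume("Sclera", shape_full_sphere(g$sclera_outer_r), lm$globe_center,
           "Sclera", parent = "World"),
    volume("Vitreous humor", shape_full_sphere(lm$r_sclera_in), lm$globe_center,
           "Vitreous humor", parent = "Sclera"),
    volume("Choroid",
           shape_sphere_section(lm$r_choroid_in, lm$r_sclera_in, ora, pi),
           lm$globe_center, "Choroid", parent = "Sclera"),
    volume("RPE", shape_sphere_section(lm$r_rpe_in, lm$r_choroid_in, ora, pi),
           lm$globe_center, "RPE", parent = "Choroid"),
    volume("NR", shape_sphere_section(lm$r_nr_in, lm$r_rpe_in, ora, pi),
           lm$globe_center, "NR", parent = "RPE"),
    volume("ILM", shape_sphere_section(lm$r_ilm_in, lm$r_nr_in, ora, pi),
           lm$globe_center, "ILM", parent = "NR"),
    volume("Cornea",
           shape_sphere_section(g$cornea_outer_r - g$cornea_thickness,
                                g$cornea_outer_r, 0, g$cornea_theta_deg * deg),
           lm$cornea_center, "Cornea", parent = "World"),
    volume("Aqueous humor",
           shape_sphere_section(0, g$cornea_outer_r - g$cornea_thickness,
                                0, g$aqueous_theta_deg * deg),
           lm$cornea_center, "Aqueous humor", parent = "Cornea"),
    volume("Iris",
           shape_tube(g$pupil_diameter / 2, g$iris_outer_r,
                      g$iris_thickness / 2),
           lm$iris_center, "Iris", parent = "Aqueous humor"),
    volume("Crystalline lens",
           shape_ellipsoid(g$lens_equatorial_diameter / 2,
                           g$lens_equatorial_diameter / 2,
                           g$lens_thickness / 2),
           lm$lens_center, "Crystalline lens", parent = "Aqueous humor")
  )

  druse_meta <- list()
  if (!is.null(drusen)) {
    for (k in seq_along(drusen)) {
      d <- drusen[[k]]
      if (is.null(d$shape) || !inherits(d$shape, "shape"))
        stop("each druse entry needs a 'shape'")
      pos <- match.arg(d$position, c("A", "B", "C", "D"))
      if (any(d$shape$params <= 0)) stop("druse dimensions must be > 0")
      h <- druse_half_depth(d$shape)
      r_center <- switch(pos,
        A = (lm$r_nr_in + lm$r_rpe_in) / 2,
        B = lm$r_nr_in + h,
        C = lm$r_rpe_in - h,
        D = lm$r_choroid_in + h)
      off <- if (is.null(d$offset)) c(0, 0) else as.numeric(d$offset)
      center <- lm$globe_center + c(off[1], off[2], -r_center)
      nm <- if (length(drusen) == 1) "Druse" else paste0("Druse", k)
      vols[[length(vols) + 1L]] <-
        volume(nm, d$shape, center, "Druse", parent = "NR")
      druse_meta[[nm]] <- list(position = pos, center = center,
                               shape = d$shape$kind, params = d$shape$params)
    }
  }

  sc <- scene(vols, meta = list(geometry = g, landmarks = lm,
                                drusen = druse_meta))
  if (validate) {
    validate_scene(sc, materials)
    if (length(druse_meta)) validate_drusen(sc, materials)
  }
  sc
}

# druse volumes must own their whole shape and sit inside the retinal
# complex (pre-flight check: "druse outside retina" is a config error)
validate_drusen <- function(sc, materials) {
  ker <- scene_for_kernel(sc, materials)
  retinal <- c("ILM", "NR", "RPE", "Choroid")
  for (i in seq_along(sc$volumes)) {
    v <- sc$volumes[[i]]
    if (!startsWith(v$name, "Druse")) next
    pts <- sample_shape_points(v, 64)
    idx <- cpp_locate(ker, pts)
    if (!all(idx == i))
      stop("scene-validation error: druse '", v$name,
           "' is not fully visible (overlapped by other volumes)")
    # points nudged outward along z must fall in retinal-layer volumes
    probe <- sweep(matrix(c(0, 0, druse_half_depth(v) + 5e-4,
                            0, 0, -(druse_half_depth(v) + 5e-4)),
                          ncol = 3, byrow = TRUE), 2, v$center, `+`)
    pidx <- cpp_locate(ker, probe)
    nm <- ifelse(pidx > 0, sc$names[pidx], NA_character_)
    if (!all(nm %in% retinal))
      stop("scene-validation error: druse '", v$name,
           "' lies outside the retinal complex (neighbours: ",
           paste(nm, collapse = ", "), ")")
  }
  invisible(TRUE)
}
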