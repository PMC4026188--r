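# Small synthetic scenes and material tables used across the transport and
# geometry tests. All are built in code; nothing is read from disk.

# a material with chosen optical constants, index-matched to air by default
test_material <- function(name, mu_a = NA, mu_s = NA, rindex = 1.0) {
  optical_properties(name, mu_a = mu_a, mu_s_reduced = mu_s, rindex = rindex)
}

# world of air plus a single slab (box) of the given material spanning
# z in [z_top - thickness, z_top], very wide in x/y
slab_scene <- function(material_name, thickness, z_top = 0, half_xy = 50,
                       world_half = c(60, 60, 60)) {
  scene(list(
    volume("World", shape_box(world_half[1], world_half[2], world_half[3]),
           c(0, 0, 0), "Air"),
    volume("Slab", shape_box(half_xy, half_xy, thickness / 2),
           c(0, 0, z_top - thickness / 2), material_name, parent = "World")
  ))
}

slab_materials <- function(slab, air_rindex = 1.0) {
  material_table(list(test_material("Air", rindex = air_rindex), slab))
}

# world + unit sphere at the origin (glass), used for intersection examples
sphere_scene <- function() {
  scene(list(
    volume("World", shape_box(30, 30, 30), c(0, 0, 0), "Air"),
    volume("Ball", shape_full_sphere(1), c(0, 0, 0), "Glass",
           parent = "World")
  ))
}

sphere_materials <- function() {
  material_table(list(test_material("Air"), test_material("Glass", rindex = 1.5)))
}

# lens-like ellipsoid (semi-axes 4.5, 4.5, 1.85) centered at the origin
ellipsoid_scene <- function() {
  scene(list(
    volume("World", shape_box(30, 30, 30), c(0, 0, 0), "Air"),
    volume("Lens", shape_ellipsoid(4.5, 4.5, 1.85), c(0, 0, 0), "Glass",
           parent = "World")
  ))
}

# reference eye scene + materials, built once per test session
eye_cache <- new.env(parent = emptyenv())
cached_eye <- function() {
  if (is.null(eye_cache$eye)) eye_cache$eye <- build_eye()
  eye_cache$eye
}

# noiseless symmetric Gaussian fixture centered exactly on a bin center,
# so the profile is bitwise mirror-symmetric about its peak
symmetric_fixture <- function(amplitude = 500, sigma = 1.2, bin = 100) {
  det <- detector("FIX", 30, 8.5, filter = "+z")
  w <- det$side_lengths[2] / det$bins
  cy <- -det$side_lengths[2] / 2 + (bin - 0.5) * w
  generate_fixture(amplitude, sigma, center = c(cy, cy), skew = 1,
                   poisson = FALSE, detector = det)
}
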