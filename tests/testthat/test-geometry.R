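# Scene construction, point location, ray-boundary queries

test_that("locate resolves nesting by the innermost-wins rule", {
  eye <- cached_eye()
  ctr <- eye$meta$landmarks$globe_center
  expect_identical(locate(eye, ctr), "Vitreous humor")
  expect_identical(locate(eye, c(0, 0, -5.45)), "Crystalline lens")
  expect_identical(locate(eye, c(3, 0, -3.3)), "Iris")
  # a point 1 m from the origin is out of the world
  expect_identical(locate(eye, c(1000, 0, 0)), NA_character_)
  # a placed 100 um druse wins over the retinal layer that hosts it
  druse <- list(shape = shape_full_sphere(0.05), position = "A")
  eye1 <- build_eye(drusen = list(druse))
  dc <- eye1$meta$drusen$Druse$center
  expect_identical(locate(eye1, dc), "Druse")
  expect_identical(locate(eye1, dc + c(0, 0, 0.06)), "NR")
})

test_that("first_intersection matches closed-form sphere/ellipsoid roots", {
  sph <- sphere_scene()
  mats <- sphere_materials()
  hit <- first_intersection(sph, c(0, 0, -2), c(0, 0, 1), materials = mats)
  expect_equal(hit$distance, 1.0, tolerance = 1e-9)
  expect_identical(hit$entered, "Ball")
  expect_lt(sum(hit$normal * c(0, 0, 1)), 0)

  ell <- ellipsoid_scene()
  inside <- first_intersection(ell, c(0, 0, 0), c(0, 0, 1),
                               materials = mats)
  expect_equal(inside$distance, 1.85, tolerance = 1e-9)
  expect_identical(inside$entered, "World")

  # entry distance from (0,0,-10): quadratic-root oracle for the ellipsoid
  o <- c(0, 0, -10); d <- c(0, 0, 1); semi <- c(4.5, 4.5, 1.85)
  qa <- sum((d / semi)^2); qb <- 2 * sum(o * d / semi^2)
  qc <- sum((o / semi)^2) - 1
  t_oracle <- (-qb - sqrt(qb^2 - 4 * qa * qc)) / (2 * qa)
  hit2 <- first_intersection(ell, o, d, materials = mats)
  expect_equal(hit2$distance, t_oracle, tolerance = 1e-9)
  expect_equal(hit2$distance, 8.15, tolerance = 1e-9)
  expect_identical(hit2$entered, "Lens")
})

test_that("direction must be normalized and origin in the world", {
  sph <- sphere_scene()
  expect_error(first_intersection(sph, c(0, 0, 0), c(0, 0, 2),
                                  materials = sphere_materials()),
               "unit vector")
  expect_error(first_intersection(sph, c(100, 0, 0), c(0, 0, 1),
                                  materials = sphere_materials()),
               "outside")
})

test_that("a convex child is exited before its parent (entry/exit pairing)", {
  sph <- sphere_scene()
  mats <- sphere_materials()
  set.seed(11)
  for (i in 1:50) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    inside <- first_intersection(sph, c(0, 0, 0), d, "Ball", mats)
    expect_identical(inside$entered, "World")
    expect_lte(inside$distance, 1 + 1e-9)  # exit before any world boundary
    expect_lt(sum(inside$normal * d), 0)   # normal convention
  }
})

test_that("ray marching agrees with dense point location (oracle equivalence)", {
  eye <- cached_eye()
  mats <- default_material_table()
  set.seed(4)
  n_rays <- 1000
  starts <- cbind(runif(n_rays, -1, 1), runif(n_rays, -1, 1),
                  runif(n_rays, -20, 0))
  keep <- !is.na(locate(eye, starts, mats))
  starts <- starts[keep, , drop = FALSE]
  for (i in seq_len(nrow(starts))) {
    p <- starts[i, ]
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    cur <- locate(eye, p, mats)
    for (step in 1:40) {
      hit <- first_intersection(eye, p, d, cur, mats)
      # the mid-segment point must locate to the current volume
      mid <- p + d * hit$distance / 2
      expect_identical(locate(eye, mid, mats), cur)
      expect_lt(sum(hit$normal * d), 0)
      if (is.na(hit$entered)) break
      p <- p + d * (hit$distance + 1e-6)
      cur2 <- locate(eye, p, mats)
      expect_identical(cur2, hit$entered)
      cur <- cur2
    }
  }
})

test_that("scene validation catches degenerate and escaping volumes", {
  expect_error(shape_full_sphere(-0.1), "> 0")
  expect_error(build_eye(drusen = list(list(shape = shape_full_sphere(-0.05),
                                            position = "A"))))
  # an oversized druse escapes the retinal complex
  expect_error(build_eye(drusen = list(list(shape = shape_full_sphere(0.4),
                                            position = "A"))),
               "scene-validation")
  # a volume outside the world box is rejected
  bad <- scene(list(
    volume("World", shape_box(5, 5, 5), c(0, 0, 0), "Air"),
    volume("Far", shape_full_sphere(1), c(20, 0, 0), "Sclera")))
  expect_error(validate_scene(bad), "outside the world")
  # a volume fully hidden by a higher-priority volume is flagged
  hidden <- scene(list(
    volume("World", shape_box(5, 5, 5), c(0, 0, 0), "Air"),
    volume("Inner", shape_full_sphere(0.5), c(0, 0, 0), "Sclera"),
    volume("Cover", shape_full_sphere(1), c(0, 0, 0), "Sclera")))
  expect_error(validate_scene(hidden), "hidden")
})

test_that("the default eye has the expected structures and lens dimensions", {
  eye <- cached_eye()
  expect_length(eye$volumes, 11)  # world + 10 eye structures
  lens <- eye$volumes[[which(eye$names == "Crystalline lens")]]
  expect_equal(lens$params, c(4.5, 4.5, 1.85))  # 9 mm diameter, 3.7 thick
  druse <- list(shape = shape_full_sphere(0.05), position = "A")
  eye1 <- build_eye(drusen = list(druse))
  expect_length(eye1$volumes, 12)
  expect_true("Druse" %in% eye1$names)
})

test_that("druse depth positions follow the growth narrative", {
  mats <- default_material_table()
  probe <- function(pos) {
    eye <- build_eye(drusen = list(list(shape = shape_full_sphere(0.05),
                                        position = pos)))
    ctr <- eye$meta$drusen$Druse$center
    h <- 0.05
    # volumes just above (toward ILM) and below (toward choroid) the druse
    c(above = locate(eye, ctr + c(0, 0, h + 1e-3), mats),
      below = locate(eye, ctr - c(0, 0, h + 1e-3), mats))
  }
  expect_identical(probe("A"), c(above = "NR", below = "NR"))
  expect_identical(probe("B"), c(above = "ILM", below = "NR"))
  expect_identical(probe("C"), c(above = "NR", below = "RPE"))
  expect_identical(probe("D"), c(above = "RPE", below = "Choroid"))
})
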