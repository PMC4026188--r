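# Profile histograms, csaps-convention smoothing, flank slopes, asymmetry

test_that("profile histogram is the per-row maximum over x", {
  det <- detector("X", 0, 2, bins = 40)
  counts <- matrix(0L, 40, 40)
  counts[10, 20] <- 7L
  g <- detector_grid(det, counts)
  pc <- profile_histogram(g)
  expect_equal(pc$values[20], 7)
  expect_equal(sum(pc$values), 7)
  expect_false(pc$empty)
  # constant grid: flat profile
  gc <- detector_grid(det, matrix(3L, 40, 40))
  expect_true(all(profile_histogram(gc)$values == 3))
  # all-zero grid is flagged empty
  expect_true(profile_histogram(detector_grid(det))$empty)
})

test_that("row-max of a separable Gaussian spot is the y-marginal Gaussian", {
  sigma <- 1.0; A <- 900
  g <- generate_fixture(A, sigma, center = c(0, 0), poisson = FALSE)
  pc <- profile_histogram(g)
  y <- pc$y_positions
  gx_max <- exp(-min(abs(y))^2 / (2 * sigma^2))  # x-factor at its nearest bin
  expect_equal(pc$values, round(A * gx_max * exp(-y^2 / (2 * sigma^2))),
               tolerance = 1e-12)
})

test_that("smoothing limits: p = 1 interpolates, p = 0 is the OLS line", {
  set.seed(9)
  v <- rpois(60, 20)
  expect_equal(smooth_profile(v, p = 1), v)
  line <- smooth_profile(v, p = 0)
  expect_equal(line, unname(fitted(lm(v ~ seq_along(v)))), tolerance = 1e-9)
})

test_that("the spline solve minimizes the csaps penalized objective", {
  # independent oracle: optimize the objective directly, measuring the
  # roughness penalty by numerical integration of the natural-spline
  # second derivative
  set.seed(14)
  x <- 1:8
  yv <- c(1, 4, 2, 8, 7, 3, 2, 5)
  p <- 0.3
  objective <- function(v) {
    f <- splinefun(x, v, method = "natural")
    grid <- seq(1, 8, length.out = 2001)
    d2 <- f(grid, deriv = 2)
    pen <- sum((d2[-1]^2 + d2[-length(d2)]^2) / 2) * diff(grid[1:2])
    p * sum((yv - v)^2) + (1 - p) * pen
  }
  opt <- optim(yv, objective, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  ours <- smooth_profile(yv, p = p)
  expect_equal(ours, opt$par, tolerance = 1e-4)
  expect_lte(objective(ours), opt$value + 1e-6)
})

test_that("default smoothing recovers a noisy Gaussian peak within one bin", {
  # a well-resolved spot (sigma ~ 6 bins); at the default smoothing the
  # peak curvature dominates 5% amplitude noise
  sigma <- 0.25; A <- 400
  det <- detector("FIX", 30, 8.5)
  w <- det$side_lengths[2] / det$bins
  cy <- -det$side_lengths[2] / 2 + (100 - 0.5) * w   # truth: bin 100
  clean <- generate_fixture(A, sigma, center = c(cy, cy), poisson = FALSE,
                            detector = det)
  pc <- profile_histogram(clean)
  set.seed(15)
  pc$values <- pmax(0, pc$values + rnorm(length(pc$values), 0, 0.05 * A))
  pc <- smooth_profile(pc, p = 0.01)
  expect_lte(abs(which.max(pc$smoothed) - 100), 1)
})

test_that("the asymmetry deviation follows its two branches", {
  expect_equal(asymmetry_deviation(2, -1), 1)    # d1 >= |d2|
  expect_equal(asymmetry_deviation(1, -2), -1)   # d1 < |d2|
  expect_equal(asymmetry_deviation(1.5, -1.5), 0)
  # sign tracks which flank is steeper
  expect_gt(asymmetry_deviation(1.2, -1), 0)
  expect_lt(asymmetry_deviation(1, -1.2), 0)
})

test_that("a symmetric profile yields y = 0 and symmetric anchors", {
  g <- symmetric_fixture()
  sp <- analyze_grid(g)
  expect_equal(sp$y, 0, tolerance = 1e-6)
  expect_equal(sp$d1, -sp$d2, tolerance = 1e-6 * abs(sp$d1))
  expect_false(sp$truncated)
  expect_identical(unname(sp$n_used), c(21L, 21L))
})

test_that("flank inflation moves y with the documented sign", {
  g <- symmetric_fixture()
  peak_bin <- 100
  # inflating the right-flank counts steepens/moves the right side: y < 0
  g_right <- g
  g_right$counts[, (peak_bin + 1):200] <-
    as.integer(round(g_right$counts[, (peak_bin + 1):200] * 1.3))
  expect_lt(analyze_grid(g_right)$y, 0)
  g_left <- g
  g_left$counts[, 1:(peak_bin - 1)] <-
    as.integer(round(g_left$counts[, 1:(peak_bin - 1)] * 1.3))
  expect_gt(analyze_grid(g_left)$y, 0)
})

test_that("a skewed fixture produces a finite positive asymmetry", {
  # right flank wider by 1.3: shallower right slope, so y > 0, and on the
  # noiseless expectation the magnitude sits well clear of the null
  g <- generate_fixture(500, 1.0, skew = 1.3, poisson = FALSE)
  y <- analyze_grid(g)$y
  expect_gt(y, 0.1)
  expect_lt(y, 0.5)
})

test_that("mirroring a grid in y negates the asymmetry exactly", {
  g <- generate_fixture(300, 0.9, center = c(0.3, -0.4), skew = 1.25,
                        seed = 4)
  y1 <- analyze_grid(g)$y
  y2 <- analyze_grid(mirror_grid_y(g))$y
  expect_equal(y2, -y1, tolerance = 1e-9)
  expect_gt(abs(y1), 0)  # non-trivial case
})

test_that("the asymmetry is invariant under count rescaling", {
  g <- generate_fixture(300, 0.9, skew = 1.2, seed = 6)
  y1 <- analyze_grid(g)$y
  g$counts <- g$counts * 7L
  expect_equal(analyze_grid(g)$y, y1, tolerance = 1e-12)
})

test_that("degenerate profiles are refused with clear errors", {
  det <- detector("X", 0, 2, bins = 40)
  empty <- detector_grid(det)
  expect_error(side_slopes(smooth_profile(profile_histogram(empty))),
               "empty")
  ramp <- detector_grid(det, matrix(rep(1:40, each = 40), 40, 40))
  expect_error(side_slopes(smooth_profile(profile_histogram(ramp), p = 1)),
               "boundary")
  pc <- profile_histogram(symmetric_fixture())
  expect_error(side_slopes(pc), "smooth")
})

test_that("compare_runs reports ratios, increases, and both asymmetries", {
  g <- generate_fixture(300, 0.9, seed = 2)
  tab <- compare_runs(list(g), list(g))
  expect_equal(tab$ratio, 1)
  expect_equal(tab$increase_pct, 0)
  g4 <- g; g4$counts <- g4$counts * 4L; g4$n_crossings <- 4 * g$n_crossings
  tab4 <- compare_runs(list(g), list(g4))
  expect_equal(tab4$ratio, 4)
  expect_equal(tab4$increase_pct, 300)
  expect_equal(tab4$y_without, tab4$y_with, tolerance = 1e-12)
  expect_error(compare_runs(list(g), list(g, g)), "mismatched")
})
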