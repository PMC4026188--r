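#' Beam-profile histogram of a detector grid
#'
#' Collapses a 2-D detector grid into the study's 1-D profile: for each
#' y-bin, the maximum count over all x-bins of that row. The profile is
#' what the asymmetry analysis operates on.
#'
#' @param grid A [detector_grid()].
#' @return An object of class `"profile_curve"`: `y_positions` (bin
#'   centers, mm, relative to the detector center), `values` (per-y
#'   maxima), `empty` flag (all-zero grid), and the source detector/run.
#' @export
profile_histogram <- function(grid) {
  stopifnot(inherits(grid, "detector_grid"))
  d <- grid$detector
  values <- apply(grid$counts, 2, max)
  w <- d$side_lengths[2] / d$bins
  y <- -d$side_lengths[2] / 2 + (seq_len(d$bins) - 0.5) * w
  structure(list(y_positions = y, values = as.numeric(values),
                 smoothed = NULL, empty = all(values == 0),
                 detector = d$name, run_index = grid$run_index),
            class = "profile_curve")
}

#' @export
print.profile_curve <- function(x, ...) {
  cat(sprintf("<profile_curve> %s run=%s: %d points, peak=%g%s%s\n",
              x$detector, x$run_index, length(x$values), max(x$values),
              if (x$empty) " [empty]" else "",
              if (!is.null(x$smoothed)) " [smoothed]" else ""))
  invisible(x)
}

# natural cubic smoothing spline values at the data sites, csaps
# parameter convention: minimize p * sum (y - f)^2 + (1 - p) * int f''^2.
# p = 1 interpolates; p = 0 degenerates to the least-squares line.
# Solution at the sites: f = (I + ((1-p)/p) K)^{-1} y with K = Q R^{-1} Q',
# Q the second-difference matrix and R the tridiagonal Gram matrix of the
# natural-spline second derivatives (Green & Silverman band form).
csaps_fit <- function(x, y, p) {
  n <- length(x)
  stopifnot(n >= 4, length(y) == n, p >= 0, p <= 1)
  if (p == 1) return(y)
  if (p == 0) return(unname(stats::fitted(stats::lm(y ~ x))))
  h <- diff(x)
  if (any(h <= 0)) stop("x must be strictly increasing")
  Q <- matrix(0, n, n - 2)
  R <- matrix(0, n - 2, n - 2)
  for (j in seq_len(n - 2)) {
    Q[j, j] <- 1 / h[j]
    Q[j + 1, j] <- -1 / h[j] - 1 / h[j + 1]
    Q[j + 2, j] <- 1 / h[j + 1]
    R[j, j] <- (h[j] + h[j + 1]) / 3
    if (j < n - 2) {
      R[j, j + 1] <- h[j + 1] / 6
      R[j + 1, j] <- h[j + 1] / 6
    }
  }
  K <- Q %*% solve(R, t(Q))
  lambda <- (1 - p) / p
  as.numeric(solve(diag(n) + lambda * K, y))
}

#' Smooth a profile curve
#'
#' Fits a natural cubic smoothing spline to the profile values under the
#' csaps parameter convention: the fit minimizes
#' `p * sum(residual^2) + (1 - p) * integral(f'')^2`,
#' so `p = 1` interpolates every point and `p = 0` collapses to the
#' least-squares straight line. The default `p = 0.01` matches the
#' smoothing used for the reflected-beam histograms. The abscissa is the
#' bin index (unit spacing), so `p` is resolution-scaled, not
#' length-scaled.
#'
#' @param curve A `"profile_curve"` from [profile_histogram()], or a
#'   numeric vector of profile values.
#' @param p Smoothing parameter in `[0, 1]`.
#' @return The curve with `$smoothed` filled (or, for a numeric input,
#'   the smoothed numeric vector).
#' @export
smooth_profile <- function(curve, p = 0.01) {
  if (is.numeric(curve)) {
    return(csaps_fit(seq_along(curve), curve, p))
  }
  stopifnot(inherits(curve, "profile_curve"))
  curve$smoothed <- csaps_fit(seq_along(curve$values), curve$values, p)
  curve$p <- p
  curve
}

#' Asymmetry deviation from a pair of flank slopes
#'
#' The study's diagnostic statistic comparing the left (`d1 > 0`) and
#' right (`d2 < 0`) flank slopes of a peaked profile:
#' `y = d1/|d2| - 1` if `d1 >= |d2|`, else `y = d2/d1 + 1`.
#' `y` is 0 iff the flanks are equally steep, positive when the left
#' flank is steeper (more photons on the right side of the profile), and
#' negative in the mirrored case.
#'
#' @param d1 Left-flank slope (positive on a peaked curve).
#' @param d2 Right-flank slope (negative).
#' @return The asymmetry deviation, dimensionless.
#' @export
asymmetry_deviation <- function(d1, d2) {
  if (d1 >= abs(d2)) d1 / abs(d2) - 1 else d2 / d1 + 1
}

#' Flank slopes and asymmetry of a smoothed profile
#'
#' On each flank of the smoothed curve's peak, finds the sample closest
#' to `height_fraction` of the peak height (above the curve baseline,
#' taken as the curve minimum) and fits an ordinary least-squares line
#' through the `window` consecutive smoothed samples centered there. The
#' two slopes give the asymmetry deviation via [asymmetry_deviation()].
#'
#' @param curve A smoothed `"profile_curve"` (see [smooth_profile()]).
#' @param height_fraction Flank anchor height as a fraction of the
#'   baseline-subtracted peak (default 0.4).
#' @param window Number of regression points per flank (default 21).
#' @return An object of class `"slope_pair"`: `d1`, `d2` (counts/mm),
#'   `y`, the anchor indices, the window actually used per flank, and a
#'   `truncated` flag set when a flank was too short for the full window.
#' @export
side_slopes <- function(curve, height_fraction = 0.4, window = 21) {
  stopifnot(inherits(curve, "profile_curve"))
  if (is.null(curve$smoothed)) stop("smooth the curve first (smooth_profile)")
  if (curve$empty) stop("empty profile: no peak to analyze")
  s <- curve$smoothed
  n <- length(s)
  peak <- which.max(s)                # ties: smallest index
  if (peak == 1 || peak == n)
    stop("profile peak lies on the boundary; no flanks to fit")
  base <- min(s)
  target <- base + height_fraction * (s[peak] - base)
  # flank search proceeds outward from the peak: the anchor is the sample
  # nearest the target height at the first downward crossing
  walk_out <- function(step) {
    i <- peak
    while (i + step >= 1 && i + step <= n && s[i] > target) i <- i + step
    prev <- min(max(i - step, 1), n)
    if (abs(s[i] - target) <= abs(s[prev] - target)) i else prev
  }
  anchor_left <- walk_out(-1L)
  anchor_right <- walk_out(1L)
  if (anchor_left == peak || anchor_right == peak)
    stop("no flank below the anchor height on one side of the peak")
  fit_flank <- function(anchor) {
    halfw <- (window - 1) %/% 2
    halfw_used <- min(halfw, anchor - 1, n - anchor)
    idx <- (anchor - halfw_used):(anchor + halfw_used)
    sl <- stats::coef(stats::lm(s[idx] ~ curve$y_positions[idx]))[2]
    list(slope = unname(sl), n_used = length(idx),
         truncated = halfw_used < halfw)
  }
  left <- fit_flank(anchor_left)
  right <- fit_flank(anchor_right)
  structure(list(d1 = left$slope, d2 = right$slope,
                 y = asymmetry_deviation(left$slope, right$slope),
                 anchor_left = anchor_left, anchor_right = anchor_right,
                 window = window,
                 n_used = c(left = left$n_used, right = right$n_used),
                 truncated = left$truncated || right$truncated,
                 height_fraction = height_fraction),
            class = "slope_pair")
}

#' @export
print.slope_pair <- function(x, ...) {
  cat(sprintf("<slope_pair> d1=%.4g d2=%.4g  y=%.4f%s\n", x$d1, x$d2, x$y,
              if (x$truncated) " [window truncated]" else ""))
  invisible(x)
}

#' Full profile analysis of a grid
#'
#' Convenience chain: [profile_histogram()] then [smooth_profile()] then
#' [side_slopes()].
#'
#' @param grid A [detector_grid()].
#' @param p Smoothing parameter (csaps convention).
#' @param height_fraction,window Flank-regression settings.
#' @return A `"slope_pair"`; the smoothed curve is attached as attribute
#'   `"curve"`.
#' @export
analyze_grid <- function(grid, p = 0.01, height_fraction = 0.4, window = 21) {
  cur <- smooth_profile(profile_histogram(grid), p)
  sp <- side_slopes(cur, height_fraction, window)
  attr(sp, "curve") <- cur
  sp
}

#' Compare matched runs with and without a druse
#'
#' Per-run comparison of two matched scan sets (same runs, same photon
#' budget): total detected counts, with/without count ratio, percentage
#' increase, and the asymmetry deviation in both scenes.
#'
#' @param grids_without,grids_with Lists of [detector_grid()] objects for
#'   the same detector, one per run, in run order.
#' @param p,height_fraction,window Analysis settings passed to
#'   [analyze_grid()].
#' @return Data frame with one row per run: `run`, `n_without`, `n_with`,
#'   `ratio`, `increase_pct`, `y_without`, `y_with`.
#' @export
compare_runs <- function(grids_without, grids_with, p = 0.01,
                         height_fraction = 0.4, window = 21) {
  if (length(grids_without) != length(grids_with))
    stop("mismatched run sets")
  rows <- lapply(seq_along(grids_without), function(i) {
    g0 <- grids_without[[i]]; g1 <- grids_with[[i]]
    if (!identical(g0$detector$name, g1$detector$name))
      stop("grids compare different detectors: ", g0$detector$name,
           " vs ", g1$detector$name)
    y0 <- tryCatch(analyze_grid(g0, p, height_fraction, window)$y,
                   error = function(e) NA_real_)
    y1 <- tryCatch(analyze_grid(g1, p, height_fraction, window)$y,
                   error = function(e) NA_real_)
    data.frame(run = if (!is.na(g0$run_index)) g0$run_index else i - 1,
               n_without = g0$n_crossings, n_with = g1$n_crossings,
               ratio = g1$n_crossings / g0$n_crossings,
               increase_pct = 100 * (g1$n_crossings - g0$n_crossings) /
                 g0$n_crossings,
               y_without = y0, y_with = y1)
  })
  do.call(rbind, rows)
}

#' Mirror a grid in y
#'
#' Utility for symmetry analyses: reflects the count matrix about the
#' detector's horizontal midline.
#'
#' @param grid A [detector_grid()].
#' @return The reflected grid.
#' @export
mirror_grid_y <- function(grid) {
  grid$counts <- grid$counts[, rev(seq_len(ncol(grid$counts)))]
  grid
}

#' Plot a smoothed profile with its flank-regression segments
#'
#' @param curve A smoothed `"profile_curve"`.
#' @param slopes Optional `"slope_pair"` from [side_slopes()].
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_profile <- function(curve, slopes = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_profile requires ggplot2")
  df <- data.frame(y = curve$y_positions, raw = curve$values,
                   smooth = curve$smoothed)
  gp <- ggplot2::ggplot(df, ggplot2::aes(x = y)) +
    ggplot2::geom_col(ggplot2::aes(y = raw), width = diff(curve$y_positions[1:2]),
                      fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = smooth), linewidth = 0.6) +
    ggplot2::labs(x = "position y (mm)", y = "max photons over x",
                  title = sprintf("%s run %s", curve$detector, curve$run_index))
  if (!is.null(slopes)) {
    halfw <- (slopes$window - 1) %/% 2
    seg <- function(anchor) {
      idx <- max(1, anchor - halfw):min(length(df$y), anchor + halfw)
      data.frame(y = df$y[idx], smooth = df$smooth[idx])
    }
    gp <- gp +
      ggplot2::geom_line(data = seg(slopes$anchor_left),
                         ggplot2::aes(y = smooth), color = "darkgreen",
                         linewidth = 1.2) +
      ggplot2::geom_line(data = seg(slopes$anchor_right),
                         ggplot2::aes(y = smooth), color = "darkgreen",
                         linewidth = 1.2)
  }
  gp
}
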