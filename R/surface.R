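#' Random sinusoidal response-surface specification
#'
#' A simulated patient response surface is the sum of 10 sinusoids per
#' stimulation parameter: for each index i and each axis (amplitude x, pulse
#' width y) a sine and a cosine term with amplitude `A ~ U(-0.5, 0.5)` and
#' frequency `F ~ U(0, 1)` cycles over the normalized length of that axis,
#'
#' `f_o(x, y) = sum_i A[i,x,sin] sin(2 pi F[i,x] x~) + A[i,x,cos] cos(2 pi F[i,x] x~)
#'            + A[i,y,sin] sin(2 pi F[i,y] y~) + A[i,y,cos] cos(2 pi F[i,y] y~)`
#'
#' with normalized coordinates `x~ = x/500`, `y~ = y/200`.
#'
#' @param amplitudes `10 x 2 x 2` array (index, axis, sin/cos) in `[-0.5, 0.5]`.
#' @param frequencies `10 x 2` matrix (index, axis) in `[0, 1]`.
#' @return An object of class `surface_spec`.
#' @export
surface_spec <- function(amplitudes, frequencies) {
  amplitudes <- array(as.double(amplitudes), dim = c(10, 2, 2))
  frequencies <- matrix(as.double(frequencies), 10, 2)
  stopifnot(
    all(abs(amplitudes) <= 0.5),
    all(frequencies >= 0 & frequencies <= 1)
  )
  structure(list(amplitudes = amplitudes, frequencies = frequencies),
            class = "surface_spec")
}

#' Sample a surface specification from the generative distribution
#'
#' Consumes the current RNG stream; wrap in [with_seed()] for reproducibility.
#'
#' @return A [surface_spec()].
#' @export
sample_surface_spec <- function() {
  surface_spec(
    amplitudes = array(stats::runif(40, -0.5, 0.5), dim = c(10, 2, 2)),
    frequencies = matrix(stats::runif(20, 0, 1), 10, 2)
  )
}

# Sum of the 20 sinusoid terms belonging to one axis, at normalized
# coordinate(s) t. axis: 1 = amplitude, 2 = pulse width.
axis_value <- function(spec, axis, t) {
  A <- spec$amplitudes
  f <- spec$frequencies[, axis]
  ang <- outer(t, 2 * pi * f) # length(t) x 10
  drop(sin(ang) %*% A[, axis, 1] + cos(ang) %*% A[, axis, 2])
}

#' Raw (unscaled) surface value
#'
#' @param spec A [surface_spec()].
#' @param x,y Amplitude (uA) and pulse width (us); vectorized.
#' @return `f_o(x, y)`.
#' @export
raw_value <- function(spec, x, y) {
  stopifnot(all(x >= 0 & x <= 500), all(y >= 0 & y <= 200))
  axis_value(spec, 1, x / 500) + axis_value(spec, 2, y / 200)
}

#' Sigmoidal edge-scaling function
#'
#' Smooth ramp that suppresses the response within a normalized distance of
#' 0.2 from the zero-dose edges and the safety boundary: 0 for `d <= 0`, 1
#' for `d >= ramp_width`, and the normalized power ramp
#' `d^e / (d^e + (ramp_width - d)^e)` in between (continuous, monotone, and
#' symmetric about the midpoint where it equals 1/2).
#'
#' @param d Distance(s), normalized units; vectorized.
#' @param ramp_width Width of the ramp (default 0.2).
#' @param exponent Ramp exponent (default 1.5).
#' @return Scale factor(s) in `[0, 1]`.
#' @export
sigmoid_scale <- function(d, ramp_width = 0.2, exponent = 1.5) {
  stopifnot(ramp_width > 0, exponent > 0)
  out <- numeric(length(d))
  out[d >= ramp_width] <- 1
  mid <- d > 0 & d < ramp_width
  if (any(mid)) {
    dm <- d[mid]
    num <- dm^exponent
    out[mid] <- num / (num + (ramp_width - dm)^exponent)
  }
  out
}

#' Modified surface value with boundary suppression
#'
#' The raw surface multiplied by the sigmoidal scale of the distances to the
#' left edge, bottom edge, and safety curve:
#' `f*(x, y) = f_o(x, y) * s(d_left) * s(d_bottom) * s(d_safe)`.
#' The top and right box edges are not suppressed.
#'
#' @param spec A [surface_spec()].
#' @param b A [safety_boundary()].
#' @param x,y Amplitude (uA) and pulse width (us); vectorized.
#' @param ramp_width,exponent Parameters of [sigmoid_scale()].
#' @return `f*(x, y)`.
#' @export
modified_value <- function(spec, b, x, y, ramp_width = 0.2, exponent = 1.5) {
  d <- boundary_distances(b, x, y)
  raw_value(spec, x, y) *
    sigmoid_scale(d$d_left, ramp_width, exponent) *
    sigmoid_scale(d$d_bottom, ramp_width, exponent) *
    sigmoid_scale(d$d_safe, ramp_width, exponent)
}

# f* evaluated on a regular nx x ny grid over the box, exploiting the
# additive separability of the raw surface. Returns list(x, y, z).
surface_grid <- function(spec, b, nx = 201, ny = 201,
                         ramp_width = 0.2, exponent = 1.5) {
  gx <- seq(0, 500, length.out = nx)
  gy <- seq(0, 200, length.out = ny)
  fx <- axis_value(spec, 1, gx / 500)
  fy <- axis_value(spec, 2, gy / 200)
  raw <- outer(fx, rep(1, ny)) + outer(rep(1, nx), fy)
  sx <- sigmoid_scale(gx / 500, ramp_width, exponent)
  sy <- sigmoid_scale(gy / 200, ramp_width, exponent)
  xx <- rep(gx, times = ny)
  yy <- rep(gy, each = nx)
  ds <- safe_distance_normalized(b, xx, yy)
  ss <- matrix(sigmoid_scale(ds, ramp_width, exponent), nx, ny)
  list(x = gx, y = gy, z = raw * outer(sx, sy) * ss)
}

#' Locate the extrema of a modified surface
#'
#' Scans f* on a regular grid and refines the best cells with bounded
#' quasi-Newton (L-BFGS-B) restarts, including a coarse lattice of starts so
#' that all sinusoidal basins (at most 10 oscillations per axis) are covered.
#'
#' @param spec A [surface_spec()].
#' @param b A [safety_boundary()].
#' @param grid_n Grid resolution per axis for the initial scan.
#' @param coarse_n Per-axis size of the additional restart lattice.
#' @param ramp_width,exponent Parameters of [sigmoid_scale()].
#' @return List with `min_location`, `min_value`, `max_location`, `max_value`
#'   (locations as `c(x, y)` in raw units).
#' @export
find_extrema <- function(spec, b, grid_n = 201, coarse_n = 5,
                         ramp_width = 0.2, exponent = 1.5) {
  g <- surface_grid(spec, b, grid_n, grid_n, ramp_width, exponent)
  fn <- function(p) modified_value(spec, b, p[1], p[2], ramp_width, exponent)

  refine <- function(starts, best_val, best_loc, direction) {
    for (i in seq_len(nrow(starts))) {
      res <- tryCatch(
        stats::optim(starts[i, ], fn, method = "L-BFGS-B",
                     lower = c(0, 0), upper = c(500, 200),
                     control = list(fnscale = direction, factr = 1e4)),
        error = function(e) NULL
      )
      if (!is.null(res) && direction * res$value < direction * best_val) {
        best_val <- res$value
        best_loc <- res$par
      }
    }
    list(value = best_val, location = best_loc)
  }

  coarse <- as.matrix(expand.grid(
    x = seq(0, 500, length.out = coarse_n),
    y = seq(0, 200, length.out = coarse_n)
  ))

  i_min <- arrayInd(which.min(g$z), dim(g$z))
  start_min <- rbind(c(g$x[i_min[1]], g$y[i_min[2]]), coarse)
  mn <- refine(start_min, min(g$z), start_min[1, ], direction = 1)

  i_max <- arrayInd(which.max(g$z), dim(g$z))
  start_max <- rbind(c(g$x[i_max[1]], g$y[i_max[2]]), coarse)
  mx <- refine(start_max, max(g$z), start_max[1, ], direction = -1)

  list(min_location = unname(mn$location), min_value = mn$value,
       max_location = unname(mx$location), max_value = mx$value)
}

#' Rescale a modified-surface value to a target effect size
#'
#' The calibrated surface is `f_R = f* / |min(f*)| * ES`, so its minimum is
#' exactly `-ES` and, with unit observation noise, the depth of the optimum
#' in noise units (Cohen's d) equals the effect size.
#'
#' @param f_star_min Minimum of f* over the box (must be negative).
#' @param effect_size Target Cohen's d (> 0).
#' @param value Value(s) of f* to rescale.
#' @return Rescaled value(s).
#' @export
rescale_to_effect_size <- function(f_star_min, effect_size, value) {
  if (!is.finite(f_star_min) || f_star_min >= 0) {
    stop("degenerate surface: minimum of f* must be negative")
  }
  stopifnot(effect_size > 0)
  value / abs(f_star_min) * effect_size
}
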