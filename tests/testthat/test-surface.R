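test_that("surface sampling respects the generative bounds and seeding", {
  specs <- with_seed(1, replicate(50, sample_surface_spec(), simplify = FALSE))
  for (s in specs) {
    expect_true(all(abs(s$amplitudes) <= 0.5))
    expect_true(all(s$frequencies >= 0 & s$frequencies <= 1))
    expect_equal(dim(s$amplitudes), c(10, 2, 2))
    expect_equal(dim(s$frequencies), c(10, 2))
  }
  expect_identical(with_seed(7, sample_surface_spec()),
                   with_seed(7, sample_surface_spec()))
})

test_that("sampled amplitudes are centered like Uniform(-0.5, 0.5)", {
  amps <- with_seed(3, {
    unlist(replicate(2500, sample_surface_spec()$amplitudes, simplify = FALSE))
  })
  n <- length(amps)
  expect_gte(n, 1e5)
  se <- sqrt(1 / 12) / sqrt(n) # SD of U(-0.5, 0.5) is 1/sqrt(12)
  expect_lt(abs(mean(amps)), 3 * se)
})

test_that("raw surface evaluation matches the sinusoid sum", {
  zero <- surface_spec(array(0, c(10, 2, 2)), matrix(0.5, 10, 2))
  expect_equal(raw_value(zero, c(0, 250, 500), c(0, 100, 200)), rep(0, 3))

  # single sine term on the amplitude axis: A = 0.5, F = 0.25, at x~ = 1
  A <- array(0, c(10, 2, 2))
  F <- matrix(0, 10, 2)
  A[1, 1, 1] <- 0.5
  F[1, 1] <- 0.25
  s <- surface_spec(A, F)
  expect_equal(raw_value(s, 500, 0), 0.5 * sin(pi / 2))

  # additive separability: f(x, y1) - f(x, y2) is independent of x
  sp <- with_seed(11, sample_surface_spec())
  xs <- c(10, 111, 222, 333, 444)
  diffs <- raw_value(sp, xs, rep(40, 5)) - raw_value(sp, xs, rep(170, 5))
  expect_equal(diffs, rep(diffs[1], 5))

  expect_error(raw_value(sp, 501, 100))
})

test_that("sigmoidal edge scaling is the normalized continuous ramp", {
  expect_identical(sigmoid_scale(-0.05), 0)
  expect_identical(sigmoid_scale(0), 0)
  expect_identical(sigmoid_scale(0.3), 1)
  expect_identical(sigmoid_scale(0.2), 1)
  expect_equal(sigmoid_scale(0.1), 0.5) # midpoint by symmetry
  d <- seq(-0.1, 0.3, by = 0.001)
  s <- sigmoid_scale(d)
  expect_true(all(diff(s) >= 0))
  expect_true(all(s >= 0 & s <= 1))
  # continuity at the ramp ends
  expect_lt(sigmoid_scale(0.1999), 1)
  expect_gt(sigmoid_scale(0.1999), 0.99)
})

test_that("modified surface is suppressed at edges and beyond the curve", {
  sp <- with_seed(13, sample_surface_spec())
  b <- ref_boundary()
  expect_equal(modified_value(sp, b, 0, 150), 0)
  expect_equal(modified_value(sp, b, 150, 0), 0)
  # beyond the safety curve: y > y_b(x)
  x <- 450
  y <- boundary_height(b, x) + 5
  expect_lte(y, 200)
  expect_equal(modified_value(sp, b, x, y), 0)
  # far from every boundary: equals the raw value
  d <- boundary_distances(b, 250, 100)
  expect_true(all(c(d$d_left, d$d_bottom, d$d_safe) > 0.2))
  expect_equal(modified_value(sp, b, 250, 100), raw_value(sp, 250, 100))
})

test_that("extrema search recovers an engineered single-basin minimum", {
  sp <- single_basin_spec()
  b <- far_boundary()
  ex <- find_extrema(sp, b)
  # oracle: dense grid scan refined by local search from the best cell
  g <- neurobo:::surface_grid(sp, b, 401, 401)
  i <- arrayInd(which.min(g$z), dim(g$z))
  ref <- stats::optim(c(g$x[i[1]], g$y[i[2]]),
                      function(p) modified_value(sp, b, p[1], p[2]),
                      method = "L-BFGS-B", lower = c(0, 0), upper = c(500, 200))
  expect_lt(abs(ex$min_value - ref$value), 1e-3)
  expect_lt(sqrt(sum(((ex$min_location - ref$par) / c(500, 200))^2)), 1e-3)
  # the basin itself is where it was engineered to be
  expect_equal(ex$min_location, c(250, 100), tolerance = 0.01)
  # the reported minimum is a lower bound for the grid
  expect_lte(ex$min_value, min(g$z) + 1e-9)
})

test_that("effect-size rescaling pins the minimum at -ES", {
  expect_equal(rescale_to_effect_size(-2, 0.3, -2), -0.3)
  expect_equal(rescale_to_effect_size(-2, 0.45, 0), 0)
  # doubling all f* values leaves f_R unchanged
  vals <- c(-2, -1, 0, 0.5)
  expect_equal(rescale_to_effect_size(-4, 0.3, 2 * vals),
               rescale_to_effect_size(-2, 0.3, vals))
  expect_error(rescale_to_effect_size(0, 0.3, 1), "degenerate")
})

test_that("noisy sampling recovers the calibrated mean and unit noise", {
  pr <- test_problems(0.6, 1)[[1]]
  mu <- problem_value(pr, 250, 120)
  draws <- with_seed(5, draw_sample(pr, rep(250, 1e5), rep(120, 1e5)))
  expect_lt(abs(mean(draws) - mu), 3 / sqrt(1e5))
  expect_lt(abs(sd(draws) - 1), 0.02)
  expect_identical(with_seed(8, draw_sample(pr, 100, 50)),
                   with_seed(8, draw_sample(pr, 100, 50)))
})
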