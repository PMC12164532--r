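test_that("box intersections match hand substitution", {
  b <- ref_boundary() # h = 1000, k = 100, a = 1e4
  ints <- box_intersections(b)
  expect_equal(ints$x1, 1000 - sqrt(1e4 * 100)) # = 0
  expect_equal(ints$y1, (500 - 1000)^2 / 1e4 + 100) # = 125
  # curvature at its lower endpoint: exit through the corner
  b2 <- safety_boundary(1000, 100, (500 - 1000)^2 / (200 - 100))
  expect_equal(box_intersections(b2)$y1, 200)
})

test_that("intersections stay in range across sampled boundaries", {
  bs <- with_seed(41, replicate(1000, sample_safety_boundary(), simplify = FALSE))
  for (b in bs) {
    ints <- box_intersections(b)
    expect_true(ints$x1 >= 0 && ints$x1 <= 500)
    expect_true(ints$y1 >= 0 && ints$y1 <= 200)
  }
})

test_that("closed-form parabola arc length matches quadrature", {
  bs <- with_seed(42, replicate(100, sample_safety_boundary(), simplify = FALSE))
  for (b in bs) {
    ints <- box_intersections(b)
    lo <- ints$x1
    num <- stats::integrate(function(x) sqrt(1 + (2 * (x - b$h) / b$a)^2),
                            lo, 500, rel.tol = 1e-12)$value
    closed <- neurobo:::parabola_arclength(b, 500) -
      neurobo:::parabola_arclength(b, lo)
    expect_lt(abs(num - closed), 1e-8 * max(1, closed))
  }
})

test_that("split point balances arc length in the printed ratio", {
  bs <- with_seed(43, replicate(20, sample_safety_boundary(), simplify = FALSE))
  for (b in bs) {
    g <- warp_geometry(b)
    expect_gt(g$x_o, g$x1)
    expect_lt(g$x_o, 500)
    left <- neurobo:::parabola_arclength(b, g$x_o) -
      neurobo:::parabola_arclength(b, g$x1)
    right <- neurobo:::parabola_arclength(b, 500) -
      neurobo:::parabola_arclength(b, g$x_o)
    target <- (500 - g$x1) / (200 - g$y1)
    expect_lt(abs(left / right - target), 1e-6 * max(1, target))
    # warp direction: slope from (x_o, y_b(x_o)) to the corner
    expect_equal(g$m, (200 - boundary_height(b, g$x_o)) / (500 - g$x_o))
    expect_gt(g$m, 0)
  }
})

test_that("warp endpoint contracts hold", {
  b <- ref_boundary()
  g <- warp_geometry(b)
  # lower-edge points are fixed
  w <- warp_point(c(0, 120, 350, 0), c(70, 0, 0, 0), b, g)
  expect_equal(w$x, c(0, 120, 350, 0))
  expect_equal(w$y, c(70, 0, 0, 0))
  # safety-curve points land on the top/right box edges
  xc <- seq(box_intersections(b)$x1 + 1, 499, length.out = 40)
  yc <- boundary_height(b, xc)
  keep <- yc <= 200
  wc <- warp_point(xc[keep], yc[keep], b, g)
  expect_lt(max(pmin(abs(wc$x - 500), abs(wc$y - 200))), 1e-6)
})

test_that("points whose ray misses the in-box curve are left fixed", {
  # boundary entering the top edge well inside the box: rays through the
  # upper-left region exit through the top edge before reaching the curve
  b <- safety_boundary(1400, 50, 6000)
  g <- warp_geometry(b)
  x1 <- box_intersections(b)$x1
  p <- c(5, 195)
  expect_lt(p[1] + (200 - p[2]) / g$m, x1) # exits the top before the curve
  w <- warp_point(p[1], p[2], b, g)
  expect_identical(c(w$x, w$y), p)
})

test_that("warp and unwarp are inverse bijections on the safe region", {
  bs <- with_seed(44, replicate(5, sample_safety_boundary(), simplify = FALSE))
  for (b in bs) {
    g <- warp_geometry(b)
    pts <- with_seed(45, {
      x <- runif(4000, 0, 500)
      y <- runif(4000, 0, 200)
      ok <- is_safe(b, x, y)
      cbind(x[ok], y[ok])[1:2000, ]
    })
    w <- warp_point(pts[, 1], pts[, 2], b, g)
    u <- unwarp_point(w$x, w$y, b, g)
    expect_lt(max(abs(u$x - pts[, 1]) / 500, abs(u$y - pts[, 2]) / 200), 1e-9)
    # warped points never leave the box
    expect_true(all(w$x <= 500 + 1e-9 & w$y <= 200 + 1e-9))
  }
})

test_that("unwarping box points always lands on the safe side", {
  b <- ref_boundary()
  g <- warp_geometry(b)
  pts <- with_seed(46, cbind(runif(2000, 0, 500), runif(2000, 0, 200)))
  u <- unwarp_point(pts[, 1], pts[, 2], b, g)
  expect_true(all(is_safe(b, u$x, u$y) |
                    neurobo:::safe_distance_normalized(b, u$x, u$y) > -1e-9))
  # top-edge points with an in-box crossing unwarp onto the safety curve
  xt <- seq(box_intersections(b)$x1 + 5, g$x_o - 5, length.out = 20)
  ut <- unwarp_point(xt, rep(200, 20), b, g)
  expect_lt(max(abs(ut$y - boundary_height(b, ut$x))), 1e-6 * 200)
})
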