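test_that("initial design is the fixed low-dose lattice, safe everywhere", {
  d <- initial_design()
  expect_equal(nrow(d), 6)
  expect_true(all(d[, 1] <= 300))
  expect_true(all(d[, 2] <= 50))
  bs <- with_seed(61, replicate(1000, sample_safety_boundary(), simplify = FALSE))
  any_unsafe <- vapply(bs, function(b) {
    # zero-dose edge points are safe for every boundary (y_b >= k >= 0);
    # the 50 us points can be unsafe only for rare near-degenerate curves
    expect_true(all(is_safe(b, d[d[, 2] == 0, 1], d[d[, 2] == 0, 2])))
    !all(is_safe(b, d[, 1], d[, 2]))
  }, logical(1))
  expect_lt(mean(any_unsafe), 0.01)
})

test_that("protocol traces have the right shape and stay safe", {
  pr <- test_problems(0.6, 1)[[1]]
  cfg <- protocol_config(2, 8, "standard",
                         acquisition_config("ucb", candidate_pool = 128,
                                            restarts = 2))
  tr <- run_protocol(pr, cfg, seed = 3)
  expect_s3_class(tr, "nb_trace")
  expect_equal(nrow(tr$samples), 6 + 2 * 8)
  expect_true(all(diff(tr$samples$session) >= 0))
  expect_true(all(is_safe(pr$boundary, tr$samples$x, tr$samples$y)))
  expect_equal(nrow(tr$per_session), 2)
  # default protocol sizing: 6 + 8 x 150 samples
  dflt <- protocol_config()
  expect_equal(6 + dflt$n_sessions * dflt$trials_per_session, 1206)
})

test_that("identical seeds reproduce traces bit for bit", {
  pr <- test_problems(0.6, 1)[[1]]
  for (acq in c("ucb", "eps_greedy", "random")) {
    cfg <- protocol_config(1, 6, "standard",
                           acquisition_config(acq, candidate_pool = 64,
                                              restarts = 1, nsga_pop = 8,
                                              nsga_generations = 3))
    t1 <- run_protocol(pr, cfg, seed = 5)
    t2 <- run_protocol(pr, cfg, seed = 5)
    expect_identical(t1$samples, t2$samples)
    expect_identical(t1$per_session, t2$per_session)
  }
})

test_that("observations equal the calibrated surface plus recorded noise", {
  pr <- test_problems(0.6, 1)[[1]]
  cfg <- protocol_config(1, 5, "standard",
                         acquisition_config("max_variance",
                                            candidate_pool = 64, restarts = 1))
  tr <- run_protocol(pr, cfg, seed = 11)
  mu <- problem_value(pr, tr$samples$x, tr$samples$y)
  resid <- tr$samples$observation - mu
  # residuals reproduce the seeded noise substream exactly
  noise_seed <- derive_seed(11, "protocol/noise")
  replay <- vapply(seq_len(nrow(tr$samples)), function(i) {
    with_seed(derive_seed(noise_seed, sprintf("trial=%d", i)), rnorm(1))
  }, numeric(1))
  expect_equal(resid, replay, tolerance = 1e-12)
})

test_that("boundary-avoiding mode records warped coordinates in the box", {
  pr <- test_problems(0.1, 1)[[1]]
  cfg <- protocol_config(1, 6, "boundary_avoiding",
                         acquisition_config("max_variance",
                                            candidate_pool = 64, restarts = 1))
  tr <- run_protocol(pr, cfg, seed = 9)
  expect_true(all(is.finite(tr$samples$warped_x)))
  expect_true(all(tr$samples$warped_x >= 0 & tr$samples$warped_x <= 500))
  expect_true(all(tr$samples$warped_y >= 0 & tr$samples$warped_y <= 200))
  expect_true(all(is_safe(pr$boundary, tr$samples$x, tr$samples$y)))
  # IBBK mode never refits hyperparameters
  expect_true(all(tr$per_session$lengthscale == tr$per_session$lengthscale[1]))
})

test_that("performance is calibrated against the ground truth", {
  pr <- test_problems(0.6, 1)[[1]]
  # the true minimizer scores exactly 1 by construction
  expect_equal(problem_value(pr, pr$min_location[1], pr$min_location[2]) /
                 (-pr$effect_size), 1)
  # a GP trained on many near-noiseless surface values scores close to 1
  dom <- neurobo:::make_domain(pr, "standard")
  pts <- with_seed(14, dom$sample(400))
  raw <- dom$to_raw(pts)
  y <- problem_value(pr, raw[, 1], raw[, 2])
  gp <- gp_fit(dom$raw_to_gp(raw), y, kernel_spec("matern52", 0.2),
               noise_var = 1e-6)
  perf <- with_seed(15, performance(pr, gp, dom))
  expect_gt(perf, 0.95)
  expect_lte(perf, 1 + 1e-6)
})

test_that("boundary fraction counts edge and safety-curve samples", {
  b <- ref_boundary()
  interior <- cbind(rep(250, 4), rep(80, 4))
  expect_equal(boundary_fraction(interior, b), 0)
  edges <- cbind(c(0, 500, 100, 300), c(50, 120, 0, 200))
  expect_equal(boundary_fraction(edges, b), 1)
  # hand-built 10-sample trace with exactly 3 edge points
  ten <- rbind(interior, interior[1:3, ], cbind(c(0, 250, 500), c(10, 0, 100)))
  expect_equal(boundary_fraction(ten, b, tol = 0.01), 0.3)
  # points on the safety curve count too
  curve <- cbind(c(350, 420), boundary_height(b, c(350, 420)))
  expect_equal(boundary_fraction(curve, b), 1)
})
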