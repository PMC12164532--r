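# Shared fixtures, memoized so expensive problem sets are built once per
# test run.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# A reference boundary with clean hand-checkable numbers:
# y_b(x) = (x - 1000)^2 / 1e4 + 100; enters the box at the top-left corner.
ref_boundary <- function() safety_boundary(1000, 100, 1e4)

# A boundary strictly outside the influence band of the box interior left of
# ~x = 400 (vertex far right, steep walls), for surface tests that want the
# safety scaling out of the way.
far_boundary <- function() safety_boundary(1500, 50, (500 - 1500)^2 / (200 - 50) * 1.2)

# Deterministic single-basin surface: one sine per axis at half a cycle, so
# f_o = -sin(pi * x/500) - sin(pi * y/200) with unique interior minimum at
# (250, 100), value -2.
single_basin_spec <- function() {
  A <- array(0, c(10, 2, 2))
  F <- matrix(0, 10, 2)
  A[1, 1, 1] <- -0.5
  A[2, 1, 1] <- -0.5 # two identical terms to reach amplitude -1 per axis
  F[1, 1] <- 0.5
  F[2, 1] <- 0.5
  A[1, 2, 1] <- -0.5
  A[2, 2, 1] <- -0.5
  F[1, 2] <- 0.5
  F[2, 2] <- 0.5
  surface_spec(A, F)
}

test_problems <- function(es, n, seed = 101) {
  memo(sprintf("problems_%g_%d_%d", es, n, seed),
       generate_problem_set(effect_sizes = es, per_es = n, seed = seed))
}

# Small fitted GP on random 2-D data for posterior-property tests.
toy_gp <- function(n = 40, seed = 9, family = "matern52", lengthscale = 0.3) {
  with_seed(seed, {
    X <- matrix(stats::runif(2 * n), n, 2)
    y <- stats::rnorm(n)
    gp_fit(X, y, kernel_spec(family, lengthscale))
  })
}

# Lightweight problem stub for domain/acquisition tests that only need a
# boundary (bypasses surface generation).
stub_problem <- function(b) list(boundary = b)
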