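# Regular grid over [0,1]^d with `res` points per axis.
unit_grid <- function(d, res) {
  axes <- rep(list(seq(0, 1, length.out = res)), d)
  as.matrix(do.call(expand.grid, axes))
}

# Discretization of the boundary (faces) of [0,1]^d, `res` points per
# edge/face axis, duplicate corner/edge points removed.
unit_boundary <- function(d, res) {
  if (d == 1) {
    return(matrix(c(0, 1), ncol = 1))
  }
  faces <- list()
  ax <- seq(0, 1, length.out = res)
  for (j in seq_len(d)) {
    for (val in c(0, 1)) {
      others <- rep(list(ax), d - 1)
      face <- as.matrix(do.call(expand.grid, others))
      full <- matrix(0, nrow(face), d)
      full[, j] <- val
      full[, -j] <- face
      faces[[length(faces) + 1]] <- full
    }
  }
  unique(do.call(rbind, faces))
}

default_grid_res <- function(d) if (d <= 2) 51L else 21L

#' Boundary variance ratio of a fitted GP
#'
#' The mean posterior variance over a discretization of the boundary of the
#' unit hypercube divided by the mean posterior variance over a regular grid
#' spanning the whole space. A ratio above 1 signals the boundary
#' over-exploration pressure that drives acquisition functions to the edges;
#' with no data and a stationary kernel the ratio is exactly 1, and for the
#' boundary-vanishing IBBK it is 0.
#'
#' With `normalization = "mean"` (the default) the ratio compares the mean
#' variance per boundary point to the mean per grid point, so it is
#' independent of the discretization counts and equals exactly 1 for a
#' stationary prior with no data. With `normalization = "sum"` the ratio
#' compares total variance mass using discretizations of matched per-axis
#' resolution (boundary faces at `grid_res` points per axis), so it also
#' carries the surface-to-volume weight of the boundary; this is the variant
#' in which higher-dimensional problems show systematically larger ratios.
#'
#' @param gp A fitted [gp_fit()] object on `[0,1]^d` inputs.
#' @param dimension Input dimension d.
#' @param grid_res Grid resolution per axis (default 51 for d <= 2, 21 for
#'   d = 3).
#' @param boundary_res Boundary discretization per edge/face axis (mean
#'   normalization only; the sum normalization matches it to `grid_res`).
#' @param normalization `"mean"` or `"sum"` (see above).
#' @return The boundary variance ratio (nonnegative scalar).
#' @export
boundary_variance_ratio <- function(gp, dimension,
                                    grid_res = default_grid_res(dimension),
                                    boundary_res = 101L,
                                    normalization = c("mean", "sum")) {
  normalization <- match.arg(normalization)
  grid <- unit_grid(dimension, grid_res)
  if (normalization == "sum") boundary_res <- grid_res
  bnd <- unit_boundary(dimension, boundary_res)
  v_grid <- gp_posterior(gp, grid)$variance
  v_bnd <- gp_posterior(gp, bnd)$variance
  agg <- if (normalization == "mean") mean else sum
  if (agg(v_grid) <= 0) {
    return(if (agg(v_bnd) <= 0) 0 else Inf)
  }
  agg(v_bnd) / agg(v_grid)
}

#' Boundary samples required to balance boundary variance
#'
#' Sequentially adds observations (value 0; posterior variance does not
#' depend on observed values) at the current highest-variance boundary
#' location until the boundary variance ratio drops below 1, mirroring the
#' cost of "correcting" boundary over-exploration by sampling the boundary.
#' Ties at the argmax are broken toward the lowest lexicographic coordinate.
#'
#' @inheritParams boundary_variance_ratio
#' @param cap Maximum number of additions before giving up.
#' @return Number of boundary samples added, or `NA_integer_` if the ratio
#'   was still >= 1 after `cap` additions.
#' @export
samples_to_balance <- function(gp, dimension,
                               grid_res = default_grid_res(dimension),
                               boundary_res = 101L, cap = 2000L) {
  stopifnot(cap > 0)
  grid <- unit_grid(dimension, grid_res)
  bnd <- unit_boundary(dimension, boundary_res)
  ord <- do.call(order, as.data.frame(bnd))
  bnd <- bnd[ord, , drop = FALSE]
  added <- 0L
  repeat {
    v_grid <- mean(gp_posterior(gp, grid)$variance)
    v_bnd_all <- gp_posterior(gp, bnd)$variance
    ratio <- if (v_grid <= 0) {
      if (mean(v_bnd_all) <= 0) 0 else Inf
    } else {
      mean(v_bnd_all) / v_grid
    }
    if (ratio < 1) {
      return(added)
    }
    if (added >= cap) {
      return(NA_integer_)
    }
    pick <- which.max(v_bnd_all) # first max = lowest lexicographic point
    gp <- gp_update(gp, bnd[pick, ], 0)
    added <- added + 1L
  }
}

#' Factorial sweep of boundary-variance diagnostics
#'
#' Runs [boundary_variance_ratio()] (and optionally [samples_to_balance()])
#' over the full factorial of dimension, Sobol training-set size, kernel
#' family, and lengthscale. Training observations are all zero and the
#' kernel hyperparameters are fixed (not refit) within the sweep. The study
#' defaults are dimensions 1-3, n = 2, 4, ..., 1024, three stationary
#' families, and 20 lengthscales linearly spaced in [0.1, 0.9].
#'
#' @param dimensions Integer vector of input dimensions.
#' @param n_train Integer vector of training-set sizes (powers of 2).
#' @param families Character vector of kernel families.
#' @param lengthscales Numeric vector of lengthscales.
#' @param seed Master seed for the Sobol scrambles.
#' @param balance Also compute [samples_to_balance()] per cell (slow).
#' @param balance_cap Cap passed to [samples_to_balance()].
#' @return A data.frame with columns dimension, n_train, family,
#'   lengthscale, bvr, n_balance, seed.
#' @export
run_diagnostic_sweep <- function(dimensions = 1:3,
                                 n_train = 2^(1:10),
                                 families = c("matern52", "rbf", "rq"),
                                 lengthscales = seq(0.1, 0.9, length.out = 20),
                                 seed = 1, balance = FALSE,
                                 balance_cap = 2000L,
                                 normalization = "mean") {
  cells <- expand.grid(
    dimension = dimensions, n_train = n_train, family = families,
    lengthscale = lengthscales, stringsAsFactors = FALSE
  )
  cells$bvr <- NA_real_
  cells$n_balance <- NA_integer_
  cells$seed <- seed
  for (i in seq_len(nrow(cells))) {
    d <- cells$dimension[i]
    X <- sobol_design(cells$n_train[i], d,
                      seed = derive_seed(seed, sprintf("diag/cell=%d", i)))
    spec <- kernel_spec(cells$family[i], lengthscale = cells$lengthscale[i])
    gp <- gp_fit(X, rep(0, nrow(X)), spec)
    cells$bvr[i] <- boundary_variance_ratio(gp, d, normalization = normalization)
    if (balance) {
      cells$n_balance[i] <- samples_to_balance(gp, d, cap = balance_cap)
    }
  }
  cells
}
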