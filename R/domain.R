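# Search-domain abstraction shared by acquisition optimization and the
# protocol runner. A domain exposes a smooth box parametrization so that
# bounded quasi-Newton search never leaves the feasible region:
#
# * standard mode: parameters (x, t) with x in [0, 500], t in [0, 1], and
#   pulse width y = t * min(200, y_b(x)) — the true nonlinear safety
#   constraint becomes a box constraint along each amplitude slice.
# * boundary_avoiding mode: parameters are warped coordinates over the full
#   box [0, 500] x [0, 200]; raw stimulation parameters are recovered by
#   inverting the safety warp, which is safe by construction.
#
# GP inputs are always the normalized (possibly warped) coordinates in
# [0, 1]^2.

# Guard against roundoff from the warp inverse / local optimizers.
clamp_box <- function(raw) {
  raw[, 1] <- pmin(pmax(raw[, 1], 0), 500)
  raw[, 2] <- pmin(pmax(raw[, 2], 0), 200)
  raw
}
make_domain <- function(problem, mode = c("standard", "boundary_avoiding"),
                        geom = NULL) {
  mode <- match.arg(mode)
  b <- problem$boundary
  sample_safe <- function(n) {
    out <- matrix(NA_real_, 0, 2)
    while (nrow(out) < n) {
      x <- stats::runif(n, 0, 500)
      y <- stats::runif(n, 0, 200)
      ok <- is_safe(b, x, y)
      out <- rbind(out, cbind(x[ok], y[ok]))
    }
    out[seq_len(n), , drop = FALSE]
  }
  if (mode == "standard") {
    list(
      mode = mode,
      lower = c(0, 0), upper = c(500, 1),
      to_raw = function(P) {
        P <- as_point_matrix(P)
        ymax <- pmin(200, boundary_height(b, P[, 1]))
        clamp_box(cbind(P[, 1], P[, 2] * ymax))
      },
      raw_to_gp = function(raw) {
        raw <- as_point_matrix(raw)
        cbind(raw[, 1] / 500, raw[, 2] / 200)
      },
      sample = function(n) {
        cbind(stats::runif(n, 0, 500), stats::runif(n))
      },
      sample_safe = sample_safe
    )
  } else {
    stopifnot(inherits(geom, "warp_geometry"))
    list(
      mode = mode,
      lower = c(0, 0), upper = c(500, 200),
      to_raw = function(P) {
        P <- as_point_matrix(P)
        uw <- unwarp_point(P[, 1], P[, 2], b, geom)
        clamp_box(cbind(uw$x, uw$y))
      },
      raw_to_gp = function(raw) {
        raw <- as_point_matrix(raw)
        w <- warp_point(raw[, 1], raw[, 2], b, geom)
        cbind(w$x / 500, w$y / 200)
      },
      sample = function(n) {
        cbind(stats::runif(n, 0, 500), stats::runif(n, 0, 200))
      },
      sample_safe = sample_safe
    )
  }
}

# GP inputs for a matrix of domain parameters.
domain_to_gp <- function(domain, P) {
  if (domain$mode == "standard") {
    domain$raw_to_gp(domain$to_raw(P))
  } else {
    P <- as_point_matrix(P)
    cbind(P[, 1] / 500, P[, 2] / 200)
  }
}
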