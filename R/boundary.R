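#' Quadratic safety boundary in amplitude-pulse-width space
#'
#' The tolerability limit of stimulation is modeled as a quadratic curve
#' `y_b(x) = (x - h)^2 / a + k` in the (amplitude, pulse width) box
#' `[0, 500] uA x [0, 200] us`, approximating a constant-charge curve. Points
#' with `y <= y_b(x)` are safe (the boundary itself is inclusive); the
#' upper-right region beyond the curve is excluded as excessive charge.
#'
#' @param h Vertex abscissa, uA, in `[500, 1500]`.
#' @param k Vertex ordinate, us, in `[0, 200]`.
#' @param a Positive curvature parameter. For the curve to intersect the box
#'   it must lie in `[(500 - h)^2 / (200 - k), h^2 / (200 - k)]`.
#' @return An object of class `safety_boundary`.
#' @export
safety_boundary <- function(h, k, a) {
  stopifnot(h >= 500, h <= 1500, k >= 0, k <= 200, a > 0)
  lo <- (500 - h)^2 / (200 - k)
  hi <- h^2 / (200 - k)
  if (a < lo - 1e-9 || a > hi + 1e-9) {
    stop("curvature 'a' outside the range for which the boundary crosses the box")
  }
  structure(list(h = h, k = k, a = a), class = "safety_boundary")
}

#' Sample a random safety boundary
#'
#' `h ~ U(500, 1500)`, `k ~ U(0, 200)` and the curvature `a` uniform on the
#' interval guaranteeing the curve crosses the parameter box. Consumes the
#' current RNG stream.
#'
#' @return A [safety_boundary()].
#' @export
sample_safety_boundary <- function() {
  h <- stats::runif(1, 500, 1500)
  k <- stats::runif(1, 0, 200)
  a <- stats::runif(1, (500 - h)^2 / (200 - k), h^2 / (200 - k))
  safety_boundary(h, k, a)
}

#' Height of the safety curve at amplitude x
#'
#' @param b A [safety_boundary()].
#' @param x Amplitude(s), uA.
#' @return `y_b(x) = (x - h)^2 / a + k`, us (may exceed 200).
#' @export
boundary_height <- function(b, x) {
  (x - b$h)^2 / b$a + b$k
}

#' Is a stimulation parameter pair safe?
#'
#' @param b A [safety_boundary()].
#' @param x,y Amplitude (uA) and pulse width (us); vectorized.
#' @return Logical vector, `TRUE` iff `y <= y_b(x)` (inclusive).
#' @export
is_safe <- function(b, x, y) {
  y <= boundary_height(b, x)
}

# Signed normalized Euclidean distance from points to the safety curve.
#
# Works in normalized coordinates (x/500, y/200) where the curve is the
# parabola q(u) = alpha (u - u_h)^2 + kappa with alpha = 1250/a, u_h = h/500,
# kappa = k/200. The squared distance from (p, v) to (u, q(u)) is quartic in
# u; its stationarity condition is the depressed cubic
#   w^3 + P w + Q = 0,   w = u - u_h,
#   P = (1 + 2 alpha (kappa - v)) / (2 alpha^2),  Q = (u_h - p) / (2 alpha^2),
# solved in closed form (Cardano / trigonometric), fully vectorized.
safe_distance_normalized <- function(b, x, y) {
  p <- x / 500
  v <- y / 200
  alpha <- 1250 / b$a
  u_h <- b$h / 500
  kappa <- b$k / 200

  A2 <- 2 * alpha^2
  P <- (1 + 2 * alpha * (kappa - v)) / A2
  Q <- (u_h - p) / A2

  n <- length(p)
  roots <- matrix(NA_real_, n, 3)
  disc <- (Q / 2)^2 + (P / 3)^3

  one <- disc > 0
  if (any(one)) {
    s <- sqrt(disc[one])
    cbrt <- function(z) sign(z) * abs(z)^(1 / 3)
    roots[one, 1] <- cbrt(-Q[one] / 2 + s) + cbrt(-Q[one] / 2 - s)
  }
  if (any(!one)) {
    Pm <- P[!one]
    Qm <- Q[!one]
    r <- sqrt(pmax(-Pm / 3, 0))
    # clamp the cosine argument against roundoff at the discriminant boundary
    arg <- pmin(pmax(3 * Qm / (2 * Pm) * sqrt(-3 / Pm), -1), 1)
    phi <- acos(arg) / 3
    roots[!one, 1] <- 2 * r * cos(phi)
    roots[!one, 2] <- 2 * r * cos(phi - 2 * pi / 3)
    roots[!one, 3] <- 2 * r * cos(phi - 4 * pi / 3)
  }

  d2 <- matrix(Inf, n, 3)
  for (j in 1:3) {
    w <- roots[, j]
    ok <- !is.na(w)
    if (any(ok)) {
      u <- w[ok] + u_h
      qu <- alpha * w[ok]^2 + kappa
      d2[ok, j] <- (u - p[ok])^2 + (qu - v[ok])^2
    }
  }
  d <- sqrt(pmin(d2[, 1], d2[, 2], d2[, 3]))
  sgn <- ifelse(v <= alpha * (p - u_h)^2 + kappa, 1, -1)
  sgn * d
}

#' Normalized distances from a point to the scaled boundaries
#'
#' Returns the three distances entering the sigmoidal edge scaling of the
#' response surface, all in normalized units (amplitude / 500, pulse width /
#' 200): distance to the left edge, to the bottom edge, and the signed
#' Euclidean distance to the safety curve (positive on the safe side,
#' negative beyond it).
#'
#' @param b A [safety_boundary()].
#' @param x,y Amplitude (uA) and pulse width (us); vectorized.
#' @return A list with components `d_left`, `d_bottom`, `d_safe`.
#' @export
boundary_distances <- function(b, x, y) {
  stopifnot(all(x >= 0 & x <= 500), all(y >= 0 & y <= 200))
  list(
    d_left = x / 500,
    d_bottom = y / 200,
    d_safe = safe_distance_normalized(b, x, y)
  )
}
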