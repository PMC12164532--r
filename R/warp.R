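#' Intersections of the safety curve with the box edges
#'
#' By construction of the curvature sampling rule the safety curve always
#' enters the box through the top edge (`y = 200`) at abscissa `x1` and exits
#' through the right edge (`x = 500`) at ordinate `y1`:
#' `x1 = h - sqrt(a (200 - k))` (clamped to 0 if the curve enters through the
#' top-left corner region) and `y1 = (500 - h)^2 / a + k`.
#'
#' @param b A [safety_boundary()].
#' @return List with `x1` and `y1`.
#' @export
box_intersections <- function(b) {
  if (b$k >= 200) stop("malformed boundary: vertex above the box")
  x1 <- b$h - sqrt(b$a * (200 - b$k))
  y1 <- boundary_height(b, 500)
  if (x1 > 500 + 1e-6 || y1 > 200 + 1e-6) {
    stop("safety boundary does not intersect the parameter box")
  }
  list(x1 = min(max(x1, 0), 500), y1 = min(max(y1, 0), 200))
}

# Closed-form arc length of the parabola y = (x-h)^2/a + k from the vertex
# to abscissa x: L(u) = (a/4) (u sqrt(1+u^2) + asinh(u)), u = 2(x-h)/a.
parabola_arclength <- function(b, x) {
  u <- 2 * (x - b$h) / b$a
  b$a / 4 * (u * sqrt(1 + u^2) + asinh(u))
}

#' Warp geometry of a safety boundary
#'
#' Precomputes the quantities defining the input warp that carries the
#' safety curve onto the top/right box edges: the edge intersections
#' `(x1, y1)`, the split abscissa `x_o` at which the in-box arc of the curve
#' divides in the ratio `(500 - x1) / (200 - y1)` (solved by bracketed root
#' finding on the closed-form arc length), and the warp direction `m`, the
#' slope of the line from `(x_o, y_b(x_o))` to the corner `(500, 200)`.
#'
#' @param b A [safety_boundary()].
#' @param tol Residual tolerance for the arc-length root solve.
#' @return An object of class `warp_geometry`.
#' @export
warp_geometry <- function(b, tol = 1e-9) {
  ints <- box_intersections(b)
  x1 <- ints$x1
  y1 <- ints$y1
  if (200 - y1 < 1e-9 || 500 - x1 < 1e-9) {
    stop("degenerate warp geometry: curve passes through the box corner")
  }
  target <- (500 - x1) / (200 - y1)
  L1 <- parabola_arclength(b, x1)
  L2 <- parabola_arclength(b, 500)
  resid <- function(xo) {
    lo <- parabola_arclength(b, xo)
    (lo - L1) - target * (L2 - lo)
  }
  x_o <- stats::uniroot(resid, lower = x1, upper = 500, tol = tol)$root
  yb_o <- boundary_height(b, x_o)
  m <- (200 - yb_o) / (500 - x_o)
  if (!is.finite(m) || m <= 0) stop("degenerate warp direction")
  structure(list(x1 = x1, y1 = y1, x_o = x_o, m = m, corner = c(500, 200)),
            class = "warp_geometry")
}

# Ray bookkeeping shared by warp and unwarp. For the line of slope m through
# (x, y): start S on the bottom/left edge (backward along the ray), crossing
# C with the left branch of the safety curve, and exit E through the
# top/right box edge. All returned as abscissae; Euclidean lengths along the
# ray are abscissa differences times sqrt(1 + m^2).
ray_sections <- function(x, y, b, m) {
  # start: ray hits x = 0 at height y - m x; if that is below 0, it hits y = 0
  y_at_0 <- y - m * x
  sx <- ifelse(y_at_0 >= 0, 0, x - y / m)
  # crossing with (X-h)^2/a + k = y + m (X - x): smaller root = left branch
  bq <- 2 * b$h + b$a * m
  cq <- b$h^2 + b$a * (b$k - y + m * x)
  disc <- bq^2 - 4 * cq
  cx <- ifelse(disc >= 0, (bq - sqrt(pmax(disc, 0))) / 2, NA_real_)
  cy <- y + m * (cx - x)
  in_box <- !is.na(cx) & cx >= 0 & cx <= 500 & cy >= 0 & cy <= 200
  # exit through the first of y = 200 / x = 500 going forward
  ex <- pmin(500, x + (200 - y) / m)
  list(sx = sx, cx = cx, ex = ex, in_box = in_box)
}

#' Warp stimulation parameters toward the box edges
#'
#' Displaces a safe point along the ray of slope `m` through it so that the
#' segment of the ray between the lower (bottom/left) box edges and the
#' safety curve is stretched linearly onto the full segment up to the outer
#' (top/right) box edges: points on the lower edges stay fixed, points on the
#' safety curve land exactly on the outer edges, and the displacement is
#' `d_w = D_s * D_o / D_p` in between. Points whose ray crosses the safety
#' curve outside the box are returned unchanged.
#'
#' @param x,y Safe amplitude (uA) / pulse width (us) coordinates; vectorized.
#' @param b A [safety_boundary()].
#' @param geom The [warp_geometry()] of `b`.
#' @return A list with warped coordinates `x`, `y`.
#' @export
warp_point <- function(x, y, b, geom) {
  stopifnot(all(is_safe(b, x, y) | safe_distance_normalized(b, x, y) > -1e-9))
  rs <- ray_sections(x, y, b, geom$m)
  d_o <- x - rs$sx # abscissa-scale distances along the ray
  d_p <- rs$cx - rs$sx
  d_s <- rs$ex - rs$cx
  apply_warp <- rs$in_box & d_p > 1e-12
  shift <- ifelse(apply_warp, d_s * (d_o / d_p), 0)
  list(x = x + shift, y = y + geom$m * shift)
}

#' Invert the safety warp
#'
#' Exact inverse of [warp_point()] along the same ray: the stretched segment
#' `[0, D_p + D_s]` is compressed back onto `[0, D_p]`, so unwarped points
#' are always on the safe side of the boundary.
#'
#' @param x,y Warped coordinates inside the box; vectorized.
#' @param b A [safety_boundary()].
#' @param geom The [warp_geometry()] of `b`.
#' @return A list with unwarped coordinates `x`, `y`.
#' @export
unwarp_point <- function(x, y, b, geom) {
  rs <- ray_sections(x, y, b, geom$m)
  d_o_w <- x - rs$sx
  d_p <- rs$cx - rs$sx
  d_s <- rs$ex - rs$cx
  apply_warp <- rs$in_box & (d_p + d_s) > 1e-12
  d_o <- ifelse(apply_warp, d_o_w * d_p / (d_p + d_s), d_o_w)
  new_x <- rs$sx + d_o
  list(x = new_x, y = y - geom$m * (x - new_x))
}
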