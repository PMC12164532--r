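# Direction-number setup for the first three Sobol dimensions
# (primitive polynomials 1, x+1, x^2+x+1 with standard initial m-values),
# using 31 output bits so all bit arithmetic stays within R's integer range.
sobol_directions <- function(dim, bits = 31L) {
  m <- integer(bits)
  if (dim == 1L) {
    m[] <- 1L
  } else if (dim == 2L) {
    m[1] <- 1L
    for (k in 2:bits) m[k] <- bitwXor(2L * m[k - 1], m[k - 1])
  } else if (dim == 3L) {
    m[1] <- 1L
    m[2] <- 3L
    for (k in 3:bits) {
      m[k] <- bitwXor(bitwXor(2L * m[k - 1], 4L * m[k - 2]), m[k - 2])
    }
  } else {
    stop("Sobol directions implemented for dimensions 1-3")
  }
  # v_k = m_k * 2^(bits - k)
  vapply(seq_len(bits), function(k) m[k] * 2^(bits - k), numeric(1))
}

#' Scrambled Sobol quasi-random design
#'
#' First `n` points of a Sobol low-discrepancy sequence in `[0, 1)^d`
#' (Gray-code construction, 31 bits), with a seeded random digital-shift
#' scramble applied per dimension so that different seeds give different but
#' equally space-filling designs.
#'
#' @param n Number of points.
#' @param d Dimension, 1 to 3.
#' @param seed Integer seed for the scramble.
#' @return An `n x d` matrix of points in `[0, 1)`.
#' @export
sobol_design <- function(n, d, seed = 1) {
  stopifnot(n >= 1, d %in% 1:3)
  bits <- 31L
  shift <- with_seed(derive_seed(seed, "sobol/shift"), {
    floor(stats::runif(d) * 2^bits)
  })
  out <- matrix(0, n, d)
  for (j in seq_len(d)) {
    v <- sobol_directions(j, bits)
    x <- 0
    xs <- numeric(n)
    xs[1] <- x # i = 0: the origin
    if (n > 1) {
      for (i in 1:(n - 1)) {
        # c = index (1-based) of the lowest zero bit of i - 1
        c <- 1L
        ii <- i - 1L
        while (bitwAnd(ii, 1L) == 1L) {
          ii <- bitwShiftR(ii, 1L)
          c <- c + 1L
        }
        x <- xor_double(x, v[c])
        xs[i + 1] <- x
      }
    }
    out[, j] <- vapply(xs, xor_double, numeric(1), y = shift[j]) / 2^bits
  }
  out
}

# XOR of two nonnegative doubles holding 31-bit integer values.
xor_double <- function(x, y) {
  as.double(bitwXor(as.integer(x), as.integer(y)))
}
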