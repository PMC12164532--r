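#' Nondominated subset of a finite candidate pool
#'
#' Exact Pareto filtering for two or more objectives, all maximized: a point
#' is kept iff no other point is at least as good in every objective and
#' strictly better in one.
#'
#' @param objectives `n x k` matrix of objective values (maximized).
#' @return Integer indices of the nondominated rows.
#' @export
nondominated <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0) stop("empty candidate set")
  if (ncol(objectives) == 2) {
    # sweep in decreasing obj1: a point is dominated iff some point with
    # obj1 >= its own (and not identical) has obj2 >= its own, strict in one
    ord <- order(objectives[, 1], objectives[, 2], decreasing = TRUE)
    o1 <- objectives[ord, 1]
    o2 <- objectives[ord, 2]
    best2 <- cummax(c(-Inf, o2[-n]))
    keep <- o2 > best2
    # ties: identical rows of the sweep are all kept if the first one is
    dup <- c(FALSE, o1[-1] == o1[-n] & o2[-1] == o2[-n])
    for (i in which(dup)) keep[i] <- keep[i - 1]
    return(sort(ord[keep]))
  }
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    oi <- objectives[i, ]
    ge <- objectives >= matrix(oi, n, ncol(objectives), byrow = TRUE)
    gt <- objectives > matrix(oi, n, ncol(objectives), byrow = TRUE)
    dominators <- rowSums(ge) == ncol(objectives) & rowSums(gt) > 0
    if (any(dominators)) keep[i] <- FALSE
  }
  which(keep)
}

# Fast nondominated sorting (returns integer front rank per row, 1 = best).
nd_sort <- function(obj) {
  n <- nrow(obj)
  rank <- integer(n)
  remaining <- seq_len(n)
  r <- 1L
  while (length(remaining) > 0) {
    idx <- remaining[nondominated(obj[remaining, , drop = FALSE])]
    rank[idx] <- r
    remaining <- setdiff(remaining, idx)
    r <- r + 1L
  }
  rank
}

# Crowding distance within a front (larger = more isolated).
crowding <- function(obj) {
  n <- nrow(obj)
  d <- numeric(n)
  for (j in seq_len(ncol(obj))) {
    o <- order(obj[, j])
    rng <- obj[o[n], j] - obj[o[1], j]
    d[o[c(1, n)]] <- Inf
    if (n > 2 && rng > 0) {
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (obj[o[3:n], j] - obj[o[1:(n - 2)], j]) / rng
    }
  }
  d
}

# Compact NSGA-II over a box domain for maximized objectives.
# obj_fn: function(matrix of parameter rows) -> matrix of objective rows.
# Returns list(par, obj) of the final nondominated set.
nsga2_search <- function(obj_fn, lower, upper, pop_size = 64L,
                         generations = 40L) {
  d <- length(lower)
  span <- upper - lower
  P <- matrix(stats::runif(pop_size * d), pop_size, d)
  P <- sweep(sweep(P, 2, span, "*"), 2, lower, "+")
  OP <- obj_fn(P)

  LB <- matrix(lower, pop_size, d, byrow = TRUE)
  UB <- matrix(upper, pop_size, d, byrow = TRUE)
  SP <- matrix(span, pop_size, d, byrow = TRUE)

  for (g in seq_len(generations)) {
    rank <- nd_sort(OP)
    crowd <- numeric(nrow(OP))
    for (r in unique(rank)) {
      sel <- rank == r
      crowd[sel] <- crowding(OP[sel, , drop = FALSE])
    }
    tournament <- function() {
      i <- sample.int(pop_size, pop_size, replace = TRUE)
      j <- sample.int(pop_size, pop_size, replace = TRUE)
      ifelse(rank[i] < rank[j] |
               (rank[i] == rank[j] & crowd[i] >= crowd[j]), i, j)
    }
    A <- P[tournament(), , drop = FALSE]
    B <- P[tournament(), , drop = FALSE]
    # simulated binary crossover (eta = 15), children alternating signs
    u <- matrix(stats::runif(pop_size * d), pop_size, d)
    beta <- ifelse(u <= 0.5, (2 * u)^(1 / 16), (1 / (2 * (1 - u)))^(1 / 16))
    sgn <- rep_len(c(1, -1), pop_size)
    Q <- 0.5 * ((1 + sgn * beta) * A + (1 - sgn * beta) * B)
    # polynomial mutation (eta = 20, rate 1/d)
    mut <- matrix(stats::runif(pop_size * d) < 1 / d, pop_size, d)
    um <- matrix(stats::runif(pop_size * d), pop_size, d)
    delta <- ifelse(um < 0.5, (2 * um)^(1 / 21) - 1, 1 - (2 * (1 - um))^(1 / 21))
    Q <- Q + mut * delta * SP
    Q <- pmin(pmax(Q, LB), UB)
    OQ <- obj_fn(Q)
    Pall <- rbind(P, Q)
    Oall <- rbind(OP, OQ)
    rank_all <- nd_sort(Oall)
    crowd_all <- numeric(nrow(Oall))
    for (r in unique(rank_all)) {
      sel <- rank_all == r
      crowd_all[sel] <- crowding(Oall[sel, , drop = FALSE])
    }
    keep <- order(rank_all, -crowd_all)[seq_len(pop_size)]
    P <- Pall[keep, , drop = FALSE]
    OP <- Oall[keep, , drop = FALSE]
  }
  front <- nondominated(OP)
  list(par = P[front, , drop = FALSE], obj = OP[front, , drop = FALSE])
}
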