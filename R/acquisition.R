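#' Acquisition configuration
#'
#' Settings for the five acquisition strategies and their maximization. The
#' mixture probabilities follow the study design: epsilon-greedy takes the
#' greedy posterior-mean optimum with probability 0.1 (otherwise a random
#' Pareto-front point), and PF-GIBBON takes the GIBBON suggestion with
#' probability 0.3.
#'
#' @param name One of `"max_variance"`, `"ucb"`, `"gibbon"`, `"eps_greedy"`,
#'   `"pf_gibbon"`, or `"random"` (the uniform safe-sampling baseline).
#' @param ucb_p Failure probability in the UCB beta schedule.
#' @param eps_greedy_p Probability of the greedy choice for `eps_greedy`.
#' @param pf_gibbon_p Probability of the GIBBON choice for `pf_gibbon`.
#' @param gibbon_max_value_samples Number of Gumbel max-value samples.
#' @param restarts Local restarts for acquisition maximization.
#' @param candidate_pool Random feasible candidates seeding the maximization.
#' @param nsga_pop,nsga_generations Pareto-front evolutionary search size.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(name = c("max_variance", "ucb", "gibbon",
                                        "eps_greedy", "pf_gibbon", "random"),
                               ucb_p = 0.01, eps_greedy_p = 0.1,
                               pf_gibbon_p = 0.3,
                               gibbon_max_value_samples = 16L,
                               restarts = 8L, candidate_pool = 1024L,
                               nsga_pop = 64L, nsga_generations = 40L) {
  name <- match.arg(name)
  stopifnot(
    ucb_p > 0, ucb_p < 1,
    eps_greedy_p >= 0, eps_greedy_p <= 1,
    pf_gibbon_p >= 0, pf_gibbon_p <= 1,
    gibbon_max_value_samples >= 1, restarts >= 1, candidate_pool >= 1
  )
  structure(list(
    name = name, ucb_p = ucb_p, eps_greedy_p = eps_greedy_p,
    pf_gibbon_p = pf_gibbon_p,
    gibbon_max_value_samples = as.integer(gibbon_max_value_samples),
    restarts = as.integer(restarts),
    candidate_pool = as.integer(candidate_pool),
    nsga_pop = as.integer(nsga_pop),
    nsga_generations = as.integer(nsga_generations)
  ), class = "acquisition_config")
}

#' UCB exploration weight schedule
#'
#' `beta_t = 2 log(t^3 pi^2 / (3 p))`, the schedule carrying the theoretical
#' zero-regret guarantee; strictly increasing in the trial counter `t`.
#'
#' @param t Trial counter (>= 1), counted across sessions.
#' @param p Failure probability (default 0.01).
#' @return `beta_t`.
#' @export
ucb_beta <- function(t, p = 0.01) {
  stopifnot(all(t >= 1), p > 0, p < 1)
  2 * log(t^3 * pi^2 / (3 * p))
}

# The optimization goal is the surface MINIMUM while every acquisition
# formula is written for maximization, so scores operate on the negated
# posterior mean mu~ = -mu throughout.

#' UCB score
#'
#' `UCB = mu~ + sqrt(beta_t) sigma` on the negated posterior mean.
#'
#' @param posterior List with `mean` and `variance` (from [gp_posterior()]).
#' @param t Trial counter for the beta schedule.
#' @param p Failure probability.
#' @return Numeric score per query point.
#' @export
score_ucb <- function(posterior, t, p = 0.01) {
  -posterior$mean + sqrt(ucb_beta(t, p)) * sqrt(posterior$variance)
}

#' Maximum-variance (pure exploration) score
#'
#' @param posterior List with `mean` and `variance`.
#' @return The posterior variance per query point.
#' @export
score_max_variance <- function(posterior) {
  posterior$variance
}

# Gumbel approximation to the distribution of the posterior maximum of the
# negated mean over a candidate discretization; returns `n_samples` draws of
# the optimal value, floored at the best candidate mean.
sample_max_values <- function(gp, domain, n_samples = 16L, n_grid = 512L) {
  cand <- domain$sample(n_grid)
  post <- gp_posterior(gp, domain_to_gp(domain, cand))
  mu <- -post$mean
  sd <- sqrt(post$variance)
  lo <- max(mu)
  hi <- max(mu + 5 * sd)
  if (hi <= lo) {
    return(rep(lo, n_samples))
  }
  logcdf <- function(y) sum(stats::pnorm((y - mu) / pmax(sd, 1e-12), log.p = TRUE))
  quant <- function(q) {
    target <- log(q)
    stats::uniroot(function(y) logcdf(y) - target, lower = lo - 1e-9,
                   upper = hi, extendInt = "upX", tol = 1e-9)$root
  }
  y25 <- quant(0.25)
  y50 <- quant(0.50)
  y75 <- quant(0.75)
  l25 <- -log(-log(0.25))
  l50 <- -log(-log(0.50))
  l75 <- -log(-log(0.75))
  b <- max((y75 - y25) / (l75 - l25), 1e-12)
  a <- y50 - b * l50
  ys <- a - b * log(-log(stats::runif(n_samples)))
  pmax(ys, lo + 1e-8)
}

#' GIBBON-style max-value entropy search score
#'
#' Information-theoretic score from the max-value entropy-search family: the
#' expected reduction in uncertainty about the optimal value from observing
#' a point, averaged over Gumbel-approximated samples of the optimum,
#'
#' `alpha(x) = mean_y* [ gamma phi(gamma) / (2 Phi(gamma)) - log Phi(gamma) ]`,
#' `gamma = (y* - mu~(x)) / sigma(x)`.
#'
#' Nonnegative everywhere and exactly 0 where the posterior variance is 0.
#'
#' @param posterior List with `mean` and `variance`.
#' @param max_value_samples Numeric vector of sampled optimal values (on the
#'   negated-mean scale), e.g. from the internal Gumbel sampler.
#' @return Numeric score per query point.
#' @export
score_gibbon <- function(posterior, max_value_samples) {
  if (length(max_value_samples) == 0) stop("no max-value samples supplied")
  mu <- -posterior$mean
  sd <- sqrt(posterior$variance)
  out <- numeric(length(mu))
  pos <- sd > 1e-12
  if (any(pos)) {
    gam <- outer(1 / sd[pos], max_value_samples) -
      outer(mu[pos] / sd[pos], rep(1, length(max_value_samples)))
    gam <- pmax(gam, -6) # guard the log-CDF tail during local refinement
    cdf <- pmax(stats::pnorm(gam), 1e-12)
    val <- gam * stats::dnorm(gam) / (2 * cdf) - log(cdf)
    out[pos] <- rowMeans(val)
  }
  pmax(out, 0)
}

#' Maximize an acquisition score over a search domain
#'
#' Seeds multi-start bounded local maximization from the best members of a
#' random feasible candidate pool; the returned point is feasible and its
#' score is at least the best pool score.
#'
#' @param score_fn Function mapping a [gp_posterior()] list to scores.
#' @param gp A fitted [gp_fit()].
#' @param domain A search domain (internal; built by the protocol runner).
#' @param cfg An [acquisition_config()].
#' @return List with `par` (domain parameters), `raw` (stimulation
#'   coordinates), and `score`.
#' @export
optimize_acquisition <- function(score_fn, gp, domain, cfg = acquisition_config("ucb")) {
  pool <- domain$sample(cfg$candidate_pool)
  scores <- score_fn(gp_posterior(gp, domain_to_gp(domain, pool)))
  ord <- order(scores, decreasing = TRUE)
  best_par <- pool[ord[1], ]
  best_score <- scores[ord[1]]

  obj <- function(p) {
    s <- score_fn(gp_posterior(gp, domain_to_gp(domain, matrix(p, 1))))
    if (is.finite(s)) -s else 1e10
  }
  starts <- pool[ord[seq_len(min(cfg$restarts, nrow(pool)))], , drop = FALSE]
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = domain$lower, upper = domain$upper),
      error = function(e) NULL
    )
    if (!is.null(res) && -res$value > best_score) {
      best_score <- -res$value
      best_par <- res$par
    }
  }
  list(par = best_par, raw = drop(domain$to_raw(matrix(best_par, 1))),
       score = best_score)
}

#' Exploration-exploitation Pareto front
#'
#' Nondominated set jointly maximizing the negated posterior mean
#' (exploitation) and the posterior variance (exploration), located by an
#' NSGA-II-style evolutionary search over the domain.
#'
#' @inheritParams optimize_acquisition
#' @return List with `par` (front rows in domain parameters), `raw`, and
#'   `obj` (two-column objective matrix).
#' @export
pareto_front <- function(gp, domain, cfg = acquisition_config("eps_greedy")) {
  obj_fn <- function(P) {
    post <- gp_posterior(gp, domain_to_gp(domain, P))
    cbind(-post$mean, post$variance)
  }
  res <- nsga2_search(obj_fn, domain$lower, domain$upper,
                      pop_size = cfg$nsga_pop,
                      generations = cfg$nsga_generations)
  list(par = res$par, raw = domain$to_raw(res$par), obj = res$obj)
}

# Greedy selection: maximize the negated posterior mean.
select_greedy <- function(gp, domain, cfg) {
  optimize_acquisition(function(post) -post$mean, gp, domain, cfg)
}

#' Select the next stimulation parameters
#'
#' Dispatches on the acquisition name: pure exploration (`max_variance`),
#' UCB with the scheduled beta, GIBBON, the epsilon-greedy and PF-GIBBON
#' Pareto mixtures, or the uniform random baseline. Consumes the current RNG
#' stream for mixture coins, candidate pools, and front sampling.
#'
#' @param gp A fitted [gp_fit()].
#' @param domain A search domain.
#' @param cfg An [acquisition_config()].
#' @param t Trial counter (UCB schedule), counted across sessions.
#' @return List with `par`, `raw` (and `score` where applicable).
#' @export
select_next <- function(gp, domain, cfg, t = 1L) {
  switch(cfg$name,
    max_variance = optimize_acquisition(score_max_variance, gp, domain, cfg),
    ucb = optimize_acquisition(
      function(post) score_ucb(post, t, cfg$ucb_p), gp, domain, cfg
    ),
    gibbon = {
      mv <- sample_max_values(gp, domain, cfg$gibbon_max_value_samples)
      optimize_acquisition(function(post) score_gibbon(post, mv),
                           gp, domain, cfg)
    },
    eps_greedy = {
      if (stats::runif(1) < cfg$eps_greedy_p) {
        select_greedy(gp, domain, cfg)
      } else {
        sample_front(gp, domain, cfg)
      }
    },
    pf_gibbon = {
      if (stats::runif(1) < cfg$pf_gibbon_p) {
        mv <- sample_max_values(gp, domain, cfg$gibbon_max_value_samples)
        optimize_acquisition(function(post) score_gibbon(post, mv),
                             gp, domain, cfg)
      } else {
        sample_front(gp, domain, cfg)
      }
    },
    random = {
      raw <- domain$sample_safe(1)
      list(par = NULL, raw = drop(raw), score = NA_real_)
    },
    stop("unknown acquisition: ", cfg$name)
  )
}

# Uniform draw from the evolutionary Pareto front.
sample_front <- function(gp, domain, cfg) {
  front <- pareto_front(gp, domain, cfg)
  i <- sample.int(nrow(front$par), 1)
  list(par = front$par[i, ], raw = front$raw[i, ], score = NA_real_)
}
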