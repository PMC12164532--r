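#' Fixed low-dose initial design
#'
#' The six starting stimulation settings in the low-amplitude, low-pulse-width
#' corner of the parameter box (a 3 x 2 lattice up to 300 uA and 50 us). All
#' six points are safe under every safety boundary the generator can produce,
#' since the safety curve never dips below its vertex height within the box.
#'
#' @return A 6 x 2 matrix of (amplitude uA, pulse width us) rows.
#' @export
initial_design <- function() {
  matrix(c(
    0, 0,
    150, 0,
    300, 0,
    300, 50,
    150, 50,
    0, 50
  ), ncol = 2, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
}

#' Protocol configuration
#'
#' The study protocol: 6 initial points, then `n_sessions` blocks of
#' `trials_per_session` acquisition-selected trials, with GP lengthscale and
#' outputscale refit at each session boundary. In `boundary_avoiding` mode
#' the GP uses the iterated Brownian-bridge kernel on safety-warped inputs,
#' the acquisition is maximized over the full warped box without a nonlinear
#' constraint, and no hyperparameters are refit (the IBBK's are fixed).
#'
#' @param n_sessions Number of sessions (default 8).
#' @param trials_per_session Trials per session (default 150).
#' @param mode `"standard"` or `"boundary_avoiding"`.
#' @param acquisition An [acquisition_config()].
#' @param kernel A [kernel_spec()]; defaults to Matern 5/2 in standard mode
#'   and the IBBK in boundary-avoiding mode.
#' @param refit_hyperparameters Refit lengthscale/outputscale at session
#'   boundaries (ignored — always off — for the IBBK).
#' @param initial Matrix of starting stimulation settings (rows of
#'   amplitude, pulse width); defaults to the fixed 6-point design.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(n_sessions = 8L, trials_per_session = 150L,
                            mode = c("standard", "boundary_avoiding"),
                            acquisition = acquisition_config("ucb"),
                            kernel = NULL,
                            refit_hyperparameters = TRUE,
                            initial = initial_design()) {
  mode <- match.arg(mode)
  if (is.null(kernel)) {
    kernel <- if (mode == "boundary_avoiding") kernel_spec("ibbk")
              else kernel_spec("matern52")
  }
  initial <- as_point_matrix(initial)
  stopifnot(n_sessions >= 1, trials_per_session >= 1,
            inherits(acquisition, "acquisition_config"),
            inherits(kernel, "kernel_spec"),
            ncol(initial) == 2, nrow(initial) >= 1)
  structure(list(
    n_sessions = as.integer(n_sessions),
    trials_per_session = as.integer(trials_per_session),
    mode = mode, acquisition = acquisition, kernel = kernel,
    refit_hyperparameters = refit_hyperparameters && kernel$family != "ibbk",
    initial = initial
  ), class = "protocol_config")
}

#' Performance of the learned optimum
#'
#' Evaluates the ground-truth calibrated surface at the model's predicted
#' best parameters (the safe-region maximizer of the negated posterior mean,
#' unwarped if the GP operates in warped coordinates) and normalizes by the
#' effect size: a perfect optimizer scores 1, a zero-response boundary point
#' scores 0, and a point predicted in a positive-response region scores
#' negative.
#'
#' @param problem An [new_problem()] object.
#' @param gp A fitted [gp_fit()].
#' @param domain The search domain the GP operates on.
#' @param cfg An [acquisition_config()] (controls the argmax search).
#' @return Scalar performance.
#' @export
performance <- function(problem, gp, domain, cfg = acquisition_config("ucb")) {
  best <- select_greedy(gp, domain, cfg)
  raw <- best$raw
  if (!is_safe(problem$boundary, raw[1], raw[2])) {
    # never report an unsafe point as the learned parameter choice
    raw[2] <- min(raw[2], boundary_height(problem$boundary, raw[1]))
  }
  problem_value(problem, raw[1], raw[2]) / (-problem$effect_size)
}

#' Fraction of samples on or near a boundary
#'
#' Fraction of sampled stimulation parameters within `tol` (normalized
#' units) of any box edge or of the safety curve.
#'
#' @param samples Matrix or data.frame with raw `x`, `y` columns.
#' @param boundary A [safety_boundary()].
#' @param tol Normalized tolerance (default 0.01).
#' @return Fraction in `[0, 1]`.
#' @export
boundary_fraction <- function(samples, boundary, tol = 0.01) {
  stopifnot(tol > 0)
  x <- samples[, 1]
  y <- samples[, 2]
  xn <- x / 500
  yn <- y / 200
  on_edge <- xn <= tol | xn >= 1 - tol | yn <= tol | yn >= 1 - tol
  on_safety <- abs(safe_distance_normalized(boundary, x, y)) <= tol
  mean(on_edge | on_safety)
}

#' Run one optimization protocol
#'
#' Evaluates the 6-point initial design, then per trial conditions the GP on
#' all data, maximizes the acquisition, and draws one noisy observation; at
#' each session boundary the kernel hyperparameters are refit (standard
#' kernels only) and per-session metrics are recorded. Fully reproducible:
#' observation noise, acquisition coins, and candidate pools consume named
#' substreams derived from `seed`.
#'
#' @param problem An [new_problem()] object.
#' @param config A [protocol_config()].
#' @param seed Integer seed for the run.
#' @return An object of class `nb_trace`: list with `samples` (per-trial
#'   data.frame), `per_session` (metrics data.frame), `config`, and the
#'   final fitted `gp`.
#' @export
run_protocol <- function(problem, config = protocol_config(), seed = 1) {
  b <- problem$boundary
  geom <- if (config$mode == "boundary_avoiding") warp_geometry(b) else NULL
  domain <- make_domain(problem, config$mode, geom)

  init <- config$initial
  n_total <- nrow(init) + config$n_sessions * config$trials_per_session
  samples <- data.frame(
    trial = seq_len(n_total), session = 0L,
    x = NA_real_, y = NA_real_,
    warped_x = NA_real_, warped_y = NA_real_,
    observation = NA_real_
  )

  noise_seed <- derive_seed(seed, "protocol/noise")
  acq_seed <- derive_seed(seed, "protocol/acquisition")
  fit_seed <- derive_seed(seed, "protocol/hyperfit")

  observe <- function(i, raw) {
    obs <- with_seed(derive_seed(noise_seed, sprintf("trial=%d", i)), {
      draw_sample(problem, raw[1], raw[2])
    })
    samples$x[i] <<- raw[1]
    samples$y[i] <<- raw[2]
    if (config$mode == "boundary_avoiding") {
      w <- warp_point(raw[1], raw[2], b, geom)
      samples$warped_x[i] <<- w$x
      samples$warped_y[i] <<- w$y
    }
    samples$observation[i] <<- obs
    obs
  }

  # The random baseline is model-free random search: no surrogate is fit and
  # the learned optimum is the best observed sample's location.
  model_free <- config$acquisition$name == "random"

  spec <- config$kernel
  X <- domain$raw_to_gp(init)
  y <- vapply(seq_len(nrow(init)), function(i) observe(i, init[i, ]), numeric(1))
  if (model_free) config$refit_hyperparameters <- FALSE
  if (config$refit_hyperparameters) {
    spec <- with_seed(derive_seed(fit_seed, "session=0"), {
      fit_hyperparameters(X, y, spec)
    })
  }
  gp <- if (model_free) NULL else gp_fit(X, y, spec)

  per_session <- data.frame(
    session = seq_len(config$n_sessions),
    performance = NA_real_, boundary_fraction = NA_real_,
    lengthscale = NA_real_, outputscale = NA_real_
  )

  trial <- 0L
  for (s in seq_len(config$n_sessions)) {
    for (j in seq_len(config$trials_per_session)) {
      trial <- trial + 1L
      i <- nrow(init) + trial
      sel <- with_seed(derive_seed(acq_seed, sprintf("trial=%d", trial)), {
        select_next(gp, domain, config$acquisition, t = trial)
      })
      obs <- observe(i, sel$raw)
      samples$session[i] <- s
      if (!model_free) {
        gp <- gp_update(gp, drop(domain$raw_to_gp(matrix(sel$raw, 1))), obs)
      }
    }
    if (config$refit_hyperparameters) {
      spec <- with_seed(derive_seed(fit_seed, sprintf("session=%d", s)), {
        fit_hyperparameters(gp$X, gp$y, spec)
      })
      gp <- gp_fit(gp$X, gp$y, spec)
    }
    done <- seq_len(nrow(init) + trial)
    per_session$performance[s] <- if (model_free) {
      best <- done[which.min(samples$observation[done])]
      problem_value(problem, samples$x[best], samples$y[best]) /
        (-problem$effect_size)
    } else {
      with_seed(
        derive_seed(acq_seed, sprintf("perf/session=%d", s)),
        performance(problem, gp, domain, config$acquisition)
      )
    }
    per_session$boundary_fraction[s] <-
      boundary_fraction(cbind(samples$x[done], samples$y[done]), b)
    per_session$lengthscale[s] <- spec$lengthscale
    per_session$outputscale[s] <- spec$outputscale
  }

  structure(list(samples = samples, per_session = per_session,
                 config = config, seed = seed, gp = gp),
            class = "nb_trace")
}

#' @export
print.nb_trace <- function(x, ...) {
  last <- x$per_session[nrow(x$per_session), ]
  cat(sprintf(
    "<nb_trace> %s/%s: %d samples, final performance %.3f, boundary fraction %.3f\n",
    x$config$mode, x$config$acquisition$name, nrow(x$samples),
    last$performance, last$boundary_fraction
  ))
  invisible(x)
}

#' Run a batch of protocols and collect per-session metrics
#'
#' @param problems List of `nb_problem` objects.
#' @param config A [protocol_config()].
#' @param seed Master seed; each problem gets a derived substream.
#' @return A data.frame of metric rows (problem id, effect size, acquisition,
#'   mode, session, performance, boundary_fraction).
#' @export
run_protocol_batch <- function(problems, config = protocol_config(), seed = 1) {
  rows <- lapply(seq_along(problems), function(i) {
    tr <- run_protocol(problems[[i]], config,
                       seed = derive_seed(seed, sprintf("batch/problem=%d", i)))
    data.frame(
      problem = i,
      effect_size = problems[[i]]$effect_size,
      acquisition = config$acquisition$name,
      mode = config$mode,
      session = tr$per_session$session,
      performance = tr$per_session$performance,
      boundary_fraction = tr$per_session$boundary_fraction
    )
  })
  do.call(rbind, rows)
}
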