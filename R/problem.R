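#' Construct a fully specified simulated optimization problem
#'
#' Bundles a response surface, safety boundary, target effect size, and the
#' normalization constant / extrema recorded at generation time. Observations
#' are drawn as `N(f_R(x, y), 1)`, so the problem's Cohen's d equals the
#' effect size by construction.
#'
#' @param surface A [surface_spec()].
#' @param boundary A [safety_boundary()].
#' @param effect_size Target effect size (Cohen's d), typically in 0.1-0.6.
#' @param norm_constant `|min(f*)|`, the rescaling denominator.
#' @param min_location,min_value,max_location,max_value Extrema of f*.
#' @param seed Integer seed recorded for reproducibility.
#' @param noise_sd Observation noise SD (fixed at 1 in the study design).
#' @return An object of class `nb_problem`.
#' @export
new_problem <- function(surface, boundary, effect_size, norm_constant,
                        min_location, min_value, max_location, max_value,
                        seed, noise_sd = 1) {
  stopifnot(
    inherits(surface, "surface_spec"),
    inherits(boundary, "safety_boundary"),
    effect_size > 0,
    norm_constant > 0,
    min_value < 0,
    abs(min_value) > max_value
  )
  structure(list(
    surface = surface, boundary = boundary,
    effect_size = effect_size, norm_constant = norm_constant,
    min_location = min_location, min_value = min_value,
    max_location = max_location, max_value = max_value,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "nb_problem")
}

#' @export
print.nb_problem <- function(x, ...) {
  cat(sprintf(
    "<nb_problem> ES = %.2f, min f* = %.4f at (%.1f uA, %.1f us), max f* = %.4f, seed = %d\n",
    x$effect_size, x$min_value, x$min_location[1], x$min_location[2],
    x$max_value, x$seed
  ))
  invisible(x)
}

#' Ground-truth calibrated response at stimulation parameters
#'
#' @param problem An [new_problem()] object.
#' @param x,y Amplitude (uA) and pulse width (us); vectorized.
#' @return `f_R(x, y)`, whose minimum over the box equals `-effect_size`.
#' @export
problem_value <- function(problem, x, y) {
  rescale_to_effect_size(
    problem$min_value, problem$effect_size,
    modified_value(problem$surface, problem$boundary, x, y)
  )
}

#' Draw noisy observations of the response
#'
#' One draw per parameter pair from `N(f_R(x, y), noise_sd)`. Consumes the
#' current RNG stream.
#'
#' @inheritParams problem_value
#' @return Numeric vector of observations.
#' @export
draw_sample <- function(problem, x, y) {
  stats::rnorm(length(x), problem_value(problem, x, y), problem$noise_sd)
}

# Sample surfaces/boundaries until |min(f*)| > max(f*); consumes the RNG.
sample_accepted_problem <- function(effect_size, seed, max_reject = 1000,
                                    grid_n = 201) {
  for (i in seq_len(max_reject)) {
    spec <- sample_surface_spec()
    b <- sample_safety_boundary()
    ex <- find_extrema(spec, b, grid_n = grid_n)
    if (ex$min_value < 0 && abs(ex$min_value) > ex$max_value) {
      return(new_problem(
        surface = spec, boundary = b, effect_size = effect_size,
        norm_constant = abs(ex$min_value),
        min_location = ex$min_location, min_value = ex$min_value,
        max_location = ex$max_location, max_value = ex$max_value,
        seed = seed
      ))
    }
  }
  stop("rejection cap exceeded while sampling a problem surface")
}

#' Generate a set of calibrated optimization problems
#'
#' Samples independent surfaces and safety boundaries, rejecting any surface
#' whose modified minimum does not dominate its maximum in absolute value, and
#' records the extrema and normalization constant of each accepted problem.
#' The defaults reproduce the study conditions: 20 surfaces per effect size
#' for effect sizes 0.1-0.6, 120 problems in total.
#'
#' @param effect_sizes Numeric vector of effect sizes.
#' @param per_es Number of problems per effect size.
#' @param seed Master seed; each problem derives its own substream seed.
#' @param max_reject Cap on rejection resampling per problem.
#' @param grid_n Grid resolution used by [find_extrema()].
#' @return A list of `nb_problem` objects.
#' @export
generate_problem_set <- function(effect_sizes = seq(0.1, 0.6, by = 0.1),
                                 per_es = 20, seed = 1, max_reject = 1000,
                                 grid_n = 201) {
  problems <- vector("list", length(effect_sizes) * per_es)
  idx <- 1L
  for (es in effect_sizes) {
    for (r in seq_len(per_es)) {
      ps <- derive_seed(seed, sprintf("problem/es=%g/rep=%d", es, r))
      problems[[idx]] <- with_seed(ps, {
        sample_accepted_problem(es, seed = ps, max_reject = max_reject,
                                grid_n = grid_n)
      })
      idx <- idx + 1L
    }
  }
  problems
}

#' Serialize a problem set to JSON
#'
#' Full-precision, schema-versioned JSON so that a written and re-read
#' problem evaluates identically at every point.
#'
#' @param problems List of `nb_problem` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_problems <- function(problems, path) {
  payload <- list(
    schema = "neurobo/problems/v1",
    problems = lapply(problems, function(p) list(
      amplitudes = as.vector(p$surface$amplitudes),
      frequencies = as.vector(p$surface$frequencies),
      h = p$boundary$h, k = p$boundary$k, a = p$boundary$a,
      effect_size = p$effect_size,
      norm_constant = p$norm_constant,
      min_location = p$min_location, min_value = p$min_value,
      max_location = p$max_location, max_value = p$max_value,
      noise_sd = p$noise_sd, seed = p$seed
    ))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a problem set written by [write_problems()]
#'
#' @param path JSON file path.
#' @return A list of `nb_problem` objects.
#' @export
read_problems <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "neurobo/problems/v1")) {
    stop("unrecognized problem-set schema: ", payload$schema)
  }
  rows <- payload$problems
  lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    new_problem(
      surface = surface_spec(unlist(r$amplitudes), unlist(r$frequencies)),
      boundary = safety_boundary(r$h, r$k, r$a),
      effect_size = r$effect_size, norm_constant = r$norm_constant,
      min_location = unlist(r$min_location), min_value = r$min_value,
      max_location = unlist(r$max_location), max_value = r$max_value,
      seed = r$seed, noise_sd = r$noise_sd
    )
  })
}
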