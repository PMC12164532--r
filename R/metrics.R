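#' Regression of final performance on boundary over-sampling
#'
#' Ordinary least squares of logit-transformed performance on the percentage
#' of samples on a boundary, across protocol runs from the final session.
#' Performances are clipped into `(delta, 1 - delta)` before the logit
#' (negative performances collapse to `delta`).
#'
#' @param performance Numeric vector of final-session performances.
#' @param boundary_pct Numeric vector of boundary percentages (0-100).
#' @param delta Clipping margin (default 1e-3).
#' @return List with `slope`, `r_squared`, `p_value`, and the fitted `lm`.
#' @export
oversampling_regression <- function(performance, boundary_pct, delta = 1e-3) {
  stopifnot(length(performance) == length(boundary_pct),
            length(performance) >= 3)
  if (stats::var(boundary_pct) == 0) {
    stop("zero-variance predictor: all boundary percentages equal")
  }
  p <- pmin(pmax(performance, delta), 1 - delta)
  y <- stats::qlogis(p)
  fit <- stats::lm(y ~ boundary_pct)
  sm <- summary(fit)
  list(
    slope = unname(stats::coef(fit)[2]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    fit = fit
  )
}

#' Percentile bootstrap confidence interval for the median
#'
#' @param values Numeric vector.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @return List with `median`, `lower`, `upper`.
#' @export
median_ci <- function(values, n_boot = 1000L, conf = 0.95) {
  stopifnot(length(values) >= 1, n_boot >= 1)
  meds <- vapply(seq_len(n_boot), function(i) {
    stats::median(sample(values, length(values), replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(meds, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(median = stats::median(values), lower = qs[1], upper = qs[2])
}
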