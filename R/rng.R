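#' Derive a named substream seed from a master seed
#'
#' Runs of the simulation framework consume randomness from several logically
#' distinct sources (surface generation, observation noise, acquisition coins,
#' optimizer restarts). Each source gets its own integer seed derived
#' deterministically from the master seed and a stream label, so that e.g.
#' changing the number of acquisition restarts does not perturb the noise
#' sequence.
#'
#' @param seed Master integer seed.
#' @param stream Character label of the substream.
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(stream)) {
    # 31-bit multiplicative string hash, kept in double-precision exact range
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate code with a temporary RNG state
#'
#' Seeds the global RNG, runs `code`, and restores the previous RNG state so
#' callers' random streams are unaffected.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  code
}
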