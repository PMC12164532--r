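#' Default run configuration
#'
#' All printed study constants: effect sizes 0.1-0.6 with 20 surfaces each,
#' 8 sessions of 150 trials, Matern 5/2 surrogate, and the acquisition
#' defaults (UCB p = 0.01, epsilon-greedy p = 0.1, PF-GIBBON p = 0.3). A
#' configuration file needs to supply only a seed to reproduce the
#' paper-scale experiment.
#'
#' @return A nested list of defaults.
#' @export
default_config <- function() {
  list(
    schema = "neurobo/config/v1",
    seed = 1L,
    problems = list(
      effect_sizes = seq(0.1, 0.6, by = 0.1),
      per_es = 20L
    ),
    protocol = list(
      n_sessions = 8L,
      trials_per_session = 150L,
      mode = "standard"
    ),
    acquisition = list(
      name = "ucb", ucb_p = 0.01, eps_greedy_p = 0.1, pf_gibbon_p = 0.3,
      gibbon_max_value_samples = 16L, restarts = 8L, candidate_pool = 1024L,
      nsga_pop = 64L, nsga_generations = 40L
    ),
    kernel = list(
      family = "matern52", lengthscale = 0.5, outputscale = 1,
      rq_alpha = 2, ibbk_beta = 20L, ibbk_epsilon = 50
    )
  )
}

# Merge user values over defaults, rejecting unknown keys, recursively.
merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) return(user)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra) > 0) {
    stop("unknown configuration key(s): ",
         paste0(path, extra, collapse = ", "))
  }
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]])) {
      merge_config(defaults[[nm]], user[[nm]], paste0(path, nm, "."))
    } else {
      user[[nm]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  if (cfg$protocol$trials_per_session < 1) {
    stop("protocol.trials_per_session must be a positive integer")
  }
  if (cfg$protocol$n_sessions < 1) {
    stop("protocol.n_sessions must be a positive integer")
  }
  if (cfg$problems$per_es < 1) stop("problems.per_es must be positive")
  if (any(cfg$problems$effect_sizes <= 0)) {
    stop("problems.effect_sizes must be positive")
  }
  if (!cfg$protocol$mode %in% c("standard", "boundary_avoiding")) {
    stop("protocol.mode must be 'standard' or 'boundary_avoiding'")
  }
  cfg
}

#' Load and validate a run configuration
#'
#' Reads JSON (or YAML, if the `yaml` package is available) by file
#' extension, rejects unknown keys with field-level messages, and fills in
#' the study defaults for everything unspecified.
#'
#' @param path Path to a `.json`, `.yaml`, or `.yml` file.
#' @return A validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configurations")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(user)) user <- list()
  user$schema <- NULL
  validate_config(merge_config(default_config(), user))
}

#' Write a configuration to JSON
#'
#' Full-precision round-trippable serialization.
#'
#' @param cfg Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

# Stable md5 hash of a configuration (canonical JSON serialization).
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a run manifest
#'
#' Records the configuration hash, per-substream seeds, and produced
#' artifact paths, sufficient to reproduce any output bit-for-bit.
#'
#' @param cfg Configuration list.
#' @param artifacts Character vector of output file paths.
#' @param path Manifest output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cfg, artifacts, path) {
  manifest <- list(
    schema = "neurobo/manifest/v1",
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    substreams = list(
      problems = derive_seed(cfg$seed, "problems"),
      protocol = derive_seed(cfg$seed, "protocol"),
      diagnostics = derive_seed(cfg$seed, "diagnostics")
    ),
    artifacts = as.list(artifacts),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Write a trace or metrics table as CSV
#'
#' Stable column order, full numeric precision.
#'
#' @param df A data.frame (e.g. `nb_trace$samples` or a metrics table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
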