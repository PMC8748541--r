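#' Default pipeline configuration
#'
#' @return Nested list of all configuration keys with their defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "dropscan_out",
    simulate = TRUE,
    reference_fasta = NULL,
    replicates = 3L,
    library = list(
      n_variants = 300L,
      mean_nt_mutations = 4.5,
      n_codons = 100L,
      frac_deleterious = 0.4
    ),
    screen = list(
      occupancy = 0.10,
      incubation_min = 3,
      gate_threshold = 60,
      active_rate_mean = 100,
      inactive_rate_mean = 2,
      expression_noise_cv = 0.3,
      autofluorescence_sd = 10,
      prior_pi = 0.25,
      n_droplets = 30000L
    ),
    sequencing = list(
      depth = 8000L,
      error_rate = 0.001
    ),
    pipeline = list(
      min_read_quality = 30,
      min_mutation_count = 10,
      numbering_offset = 0L
    ),
    fit = list(
      l2_penalty = 1e-4,
      tol = 1e-8,
      max_iter = 500L,
      exclusion_threshold = 0.5
    ),
    profiles = list(
      window = 9L
    ),
    debug_shuffle_replicates = integer(0)
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, fills defaults for absent keys, rejects unknown keys
#' by name, and range-checks the values (e.g. `screen.prior_pi` must lie in
#' (0,1), `screen.occupancy` in (0,1), thresholds must be non-negative).
#' An empty or missing-section file yields all defaults.
#'
#' @param path YAML config path, or NULL for pure defaults.
#' @return Validated configuration list of class `dropscan_config`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user, key_path = character(0))
  cfg$debug_shuffle_replicates <-
    as.integer(unlist(cfg$debug_shuffle_replicates))
  validate_config(cfg)
  class(cfg) <- c("dropscan_config", "list")
  cfg
}

#' Write a configuration back to YAML
#'
#' Load -> dump -> load is idempotent.
#'
#' @param config A configuration list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1L))]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

merge_config <- function(defaults, user, key_path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown configuration key: ",
         paste(c(key_path, unknown[1L]), collapse = "."), call. = FALSE)
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]]))
        stop("configuration key '", paste(c(key_path, k), collapse = "."),
             "' must be a mapping", call. = FALSE)
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], c(key_path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  check <- function(ok, key, msg) {
    if (!ok) stop("invalid configuration key '", key, "': ", msg,
                  call. = FALSE)
  }
  check(cfg$screen$prior_pi > 0 && cfg$screen$prior_pi < 1,
        "screen.prior_pi", "must be in (0, 1)")
  check(cfg$screen$occupancy > 0 && cfg$screen$occupancy < 1,
        "screen.occupancy", "must be in (0, 1)")
  check(cfg$pipeline$min_read_quality >= 0,
        "pipeline.min_read_quality", "must be >= 0")
  check(cfg$pipeline$min_mutation_count >= 0,
        "pipeline.min_mutation_count", "must be >= 0")
  check(cfg$sequencing$error_rate >= 0 && cfg$sequencing$error_rate < 0.1,
        "sequencing.error_rate", "must be in [0, 0.1)")
  check(cfg$library$n_variants >= 1, "library.n_variants", "must be >= 1")
  check(cfg$library$mean_nt_mutations >= 0,
        "library.mean_nt_mutations", "must be >= 0")
  check(cfg$replicates >= 1, "replicates", "must be >= 1")
  check(cfg$profiles$window %% 2L == 1L, "profiles.window", "must be odd")
  check(cfg$fit$l2_penalty >= 0, "fit.l2_penalty", "must be >= 0")
  invisible(cfg)
}
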