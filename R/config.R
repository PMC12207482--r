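# YAML run configuration: one file describes a full reproducible run.

default_config <- function() {
  list(
    seed = 1L,
    focal = list(omega = 0.5, s = 0.5, b = 0.5),
    population = list(rho = 0.5, tau = 0.5),
    community = list(size = 20L, training_bias = 0),
    episode = list(n_coplayers = 5L, n_races = 8L),
    payoffs = list(R = 4, T = 3, P = 3, S = 1),
    intervention = NULL,
    sweep = list(s_n = 21L, omega_n = 21L, b_n = 11L, race = 8L),
    episodes = 600L
  )
}

prob_fields <- c("focal.omega", "focal.s", "focal.b",
                 "population.rho", "population.tau",
                 "community.training_bias")

merge_config <- function(base, user, path = character()) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(base)) {
      stop(sprintf("unknown config field `%s`", full), call. = FALSE)
    }
    if (is.list(base[[key]]) && is.list(user[[key]])) {
      base[[key]] <- merge_config(base[[key]], user[[key]], c(path, key))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

validate_config <- function(cfg) {
  for (f in prob_fields) {
    parts <- strsplit(f, ".", fixed = TRUE)[[1]]
    val <- cfg[[parts[1]]][[parts[2]]]
    if (!is.numeric(val) || length(val) != 1L || is.na(val) ||
        val < 0 || val > 1) {
      stop(sprintf("config field `%s` must be a probability in [0, 1]", f),
           call. = FALSE)
    }
  }
  for (f in c("community.size", "episode.n_coplayers", "episode.n_races")) {
    parts <- strsplit(f, ".", fixed = TRUE)[[1]]
    val <- cfg[[parts[1]]][[parts[2]]]
    if (!is.numeric(val) || length(val) != 1L || is.na(val) || val < 1 ||
        val != floor(val)) {
      stop(sprintf("config field `%s` must be a positive integer", f),
           call. = FALSE)
    }
  }
  p <- cfg$payoffs
  if (!(p$R > p$T && p$T >= p$P && p$P > p$S)) {
    stop("config field `payoffs` must satisfy R > T >= P > S", call. = FALSE)
  }
  if (!is.null(cfg$intervention)) {
    bt <- cfg$intervention$beta
    if (!is.numeric(bt) || length(bt) != 1L || is.na(bt) || bt < 0) {
      stop("config field `intervention.beta` must be nonnegative",
           call. = FALSE)
    }
    extra <- setdiff(names(cfg$intervention),
                     c("beta", "coop_threshold", "availability"))
    if (length(extra)) {
      stop(sprintf("unknown config field `intervention.%s`", extra[1]),
           call. = FALSE)
    }
  }
  if (!is.numeric(cfg$episodes) || cfg$episodes < 1) {
    stop("config field `episodes` must be a positive integer", call. = FALSE)
  }
  # keep the (possibly NULL) intervention slot so YAML round trips compare
  # equal even though YAML drops null keys
  if (!"intervention" %in% names(cfg)) cfg["intervention"] <- list(NULL)
  cfg <- cfg[names(default_config())]
  structure(cfg, class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration file, fills in documented defaults for absent
#' fields, rejects unknown fields, and validates every value (probabilities
#' in `[0, 1]`, positive integer counts, the Stag hunt payoff ordering).
#' Top-level sections: `seed`, `focal` (omega, s, b), `population`
#' (rho, tau), `community` (size, training_bias), `episode` (n_coplayers,
#' n_races), `payoffs` (R, T, P, S), `intervention` (beta, optional),
#' `sweep` (grid resolutions), `episodes`.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list.
#' @seealso [save_config()] for the round-trip inverse.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user)
  validate_config(cfg)
}

#' Save a run configuration to YAML
#'
#' @param cfg A `run_config` (or compatible list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Stable hash of a run configuration
#'
#' Used in result-file metadata so that every output can be traced back to
#' the exact configuration and seed that produced it.
#'
#' @param cfg A `run_config` (or any R object).
#' @return A character hash.
#' @export
config_hash <- function(cfg) {
  rlang::hash(unclass(cfg))
}

config_focal <- function(cfg) {
  focal_params(cfg$focal$omega, cfg$focal$s, cfg$focal$b)
}

config_population <- function(cfg) {
  population_params(cfg$population$rho, cfg$population$tau)
}

config_intervention <- function(cfg) {
  if (is.null(cfg$intervention)) return(NULL)
  intervention_spec(
    beta = cfg$intervention$beta,
    coop_threshold = cfg$intervention$coop_threshold %||% 0.75,
    availability = cfg$intervention$availability
  )
}

config_payoffs <- function(cfg) {
  stag_hunt_payoffs(cfg$payoffs$R, cfg$payoffs$T, cfg$payoffs$P,
                    cfg$payoffs$S)
}
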