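# Parameter sweeps: the (s, omega) contour of the discrimination index
# averaged over color bias, training-bias sweeps against an unbiased
# evaluation community, and the random-choice calibration baselines.

#' Discrimination-index sweep over stickiness and awareness
#'
#' For every `(s, omega, b)` combination, computes the discrimination index
#' of the association distribution after `race` recursion steps (default 8,
#' i.e. `P(8)`). In `"analytic"` mode the recursion is evaluated exactly and
#' the result is deterministic; in `"simulated"` mode each cell is estimated
#' from infinite-population Monte-Carlo episodes with a bootstrap standard
#' error. Averaging over `b` (see [sweep_surface()]) gives the
#' awareness-stickiness contour: the unweighted mean of D over the `b` grid.
#'
#' @param s,omega Grid values for stickiness and awareness (each in
#'   `[0, 1]`).
#' @param b Color-bias values averaged over (default 11 evenly spaced
#'   points).
#' @param pop A [population_params()]; defaults to the unbiased evaluation
#'   composition `rho = tau = 0.5` (the measurement context).
#' @param race Recursion depth at which D is read off.
#' @param mode `"analytic"` or `"simulated"`.
#' @param episodes Episodes per cell in simulated mode.
#' @param n_boot Bootstrap resamples for the simulated-mode standard error.
#' @param seed Optional seed (simulated mode).
#' @return A tibble of class `sweep_result`, long over `(s, omega, b)`, with
#'   column `d` (and `se` in simulated mode). The `race` and `mode` used are
#'   stored as attributes.
#' @examples
#' sw <- contour_sweep(s = c(0, 0.5, 1), omega = c(0, 0.5, 1), b = c(0.25, 0.75))
#' sweep_surface(sw)
#' @export
contour_sweep <- function(s = seq(0, 1, length.out = 21),
                          omega = seq(0, 1, length.out = 21),
                          b = seq(0, 1, length.out = 11),
                          pop = population_params(0.5, 0.5),
                          race = 8,
                          mode = c("analytic", "simulated"),
                          episodes = 5000, n_boot = 200, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(pop, "population_params"))
  race <- check_count(race, "race", min = 0L)
  for (v in list(s = s, omega = omega, b = b)) {
    if (any(v < 0 | v > 1)) stop("grid values must lie in [0, 1]", call. = FALSE)
  }
  grid <- tidyr::expand_grid(s = s, omega = omega, b = b)

  if (mode == "analytic") {
    grid$d <- purrr::pmap_dbl(grid, function(s, omega, b) {
      P <- p_recursion(omega, s, b, pop$rho, pop$tau, race)[race + 1L, ]
      d_index_num(P[1L], P[2L], P[3L], P[4L])
    })
  } else {
    local_seed_if(seed)
    cell_seeds <- child_seeds(sample.int(2147483646L, 1L), nrow(grid))
    est <- purrr::pmap(
      cbind(grid, .seed = cell_seeds),
      function(s, omega, b, .seed) {
        rec <- run_episodes(episodes, focal_params(omega, s, b), pop = pop,
                            mode = "infinite", n_races = race + 1L,
                            seed = .seed)
        tr <- discrimination_trace(rec[rec$race == race, ], n_boot = n_boot,
                                   seed = .seed)
        bw <- (tr$ci_high - tr$ci_low) / (2 * stats::qnorm(0.975))
        tibble::tibble(d = tr$d, se = bw)
      })
    grid <- dplyr::bind_cols(grid, dplyr::bind_rows(est))
  }
  structure(grid, class = c("sweep_result", class(grid)),
            race = race, mode = mode,
            pop = c(rho = pop$rho, tau = pop$tau))
}

#' Average a sweep over the color-bias grid
#'
#' @param x A `sweep_result` from [contour_sweep()].
#' @return A tibble with one row per `(s, omega)` and the unweighted mean
#'   `d_mean` over the `b` values (plus `se_mean` in simulated mode).
#' @export
sweep_surface <- function(x) {
  stopifnot(inherits(x, "sweep_result"))
  out <- x |>
    dplyr::group_by(.data$s, .data$omega) |>
    dplyr::summarise(
      d_mean = mean(.data$d),
      se_mean = if ("se" %in% names(x)) {
        sqrt(sum(.data$se^2)) / dplyr::n()
      } else NA_real_,
      .groups = "drop")
  if (all(is.na(out$se_mean))) out$se_mean <- NULL
  out
}

#' Training-bias sweep in the unbiased evaluation community
#'
#' Mirrors the frozen-agent evaluation protocol: for each training bias `c`,
#' a focal whose color bias is `b = (1 + c)/2` (the probability of picking
#' the color that correlated with cooperation during training; `c = 0` gives
#' a color-blind `b = 0.5`, `c = 1` an always-purple `b = 1`) plays
#' `episodes` episodes against a zero-correlation evaluation community, and
#' the per-race discrimination index is reported with bootstrap confidence
#' intervals.
#'
#' @param biases Training-bias values in `[0, 1]`.
#' @param omega,s Focal awareness and stickiness.
#' @param episodes Episodes per bias (default 600, the evaluation protocol).
#' @param community Evaluation roster (default size 20, zero correlation).
#' @param n_coplayers,n_races Episode shape (defaults 5 and 8).
#' @param intervention An [intervention_spec()] or `NULL`.
#' @param n_boot Bootstrap resamples for the confidence intervals.
#' @param level Confidence level.
#' @param seed Optional integer seed.
#' @return A tibble with columns `bias`, `race`, `d`, `ci_low`, `ci_high`,
#'   `n_episodes`.
#' @export
bias_sweep <- function(biases = seq(0, 1, by = 0.25), omega = 0, s = 0,
                       episodes = 600, community = make_community(20, 0),
                       n_coplayers = 5, n_races = 8, intervention = NULL,
                       n_boot = 5000, level = 0.95, seed = NULL) {
  if (any(biases < 0 | biases > 1)) {
    stop("`biases` must lie in [0, 1]", call. = FALSE)
  }
  local_seed_if(seed)
  bias_seeds <- child_seeds(sample.int(2147483646L, 1L), length(biases))
  purrr::map2(biases, bias_seeds, function(bb, sd) {
    rec <- run_episodes(episodes, focal_params(omega, s, b = (1 + bb) / 2),
                        community = community, n_coplayers = n_coplayers,
                        n_races = n_races, intervention = intervention,
                        seed = sd)
    tr <- discrimination_trace(rec, n_boot = n_boot, level = level, seed = sd)
    dplyr::mutate(tibble::as_tibble(tr), bias = bb, .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' Random-choice calibration baselines
#'
#' Simulates a focal that picks uniformly among its coplayers in a
#' zero-correlation evaluation community and reports the Monte-Carlo
#' estimates of empirical awareness and stickiness with binomial standard
#' errors. With half the community cooperating, the expected awareness is
#' 0.5; with `k` coplayers, the probability of repeating the previous
#' partner is exactly `1/k` (0.2 for the default 5).
#'
#' @param n_episodes Number of episodes (default 20000).
#' @param community Evaluation roster.
#' @param n_coplayers,n_races Episode shape (defaults 5 and 8).
#' @param seed Optional integer seed.
#' @return A one-row tibble with `awareness_hat`, `se_awareness`,
#'   `stickiness_hat`, `se_stickiness`, `n_episodes`, `n_races`, `n_pairs`.
#' @examples
#' random_baselines(n_episodes = 500, seed = 1)
#' @export
random_baselines <- function(n_episodes = 20000,
                             community = make_community(20, 0),
                             n_coplayers = 5, n_races = 8, seed = NULL) {
  rec <- run_episodes(n_episodes, community = community, policy = "random",
                      n_coplayers = n_coplayers, n_races = n_races,
                      seed = seed)
  beh <- empirical_behavior(rec)
  dplyr::mutate(
    beh,
    se_awareness = sqrt(.data$awareness_hat * (1 - .data$awareness_hat) /
                          .data$n_races),
    se_stickiness = sqrt(.data$stickiness_hat * (1 - .data$stickiness_hat) /
                           .data$n_pairs),
    n_episodes = n_episodes,
    .after = "stickiness_hat"
  )
}

#' Analytic stickiness of a uniform-random chooser
#'
#' With `k` coplayers and uniform independent choices, the previous partner
#' is re-chosen with probability exactly `1/k`.
#'
#' @param n_coplayers Number of coplayers (default 5).
#' @return The probability `1/n_coplayers`.
#' @export
random_choice_stickiness <- function(n_coplayers = 5) {
  1 / check_count(n_coplayers, "n_coplayers", min = 1L)
}
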