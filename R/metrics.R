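# The discrimination index and its estimation from simulated episodes.

d_index_num <- function(p_pc, p_pd, p_tc, p_td) {
  (abs(p_pc - p_pd) + abs(p_tc - p_td)) - (abs(p_pc - p_tc) + abs(p_pd - p_td))
}

#' Discrimination index
#'
#' For an association distribution `P` over partner types (a 2x2 matrix of
#' proportions, colors by rows and strategies by columns), the discrimination
#' index is the sum of absolute differences across columns minus the sum of
#' absolute differences across rows:
#' \deqn{D = (|P_{pc}-P_{pd}| + |P_{tc}-P_{td}|) - (|P_{pc}-P_{tc}| + |P_{pd}-P_{td}|).}
#' `D > 0` means the focal associates by partner behavior, `D < 0` by partner
#' color; `D = 0` means any oversampling of a color is accounted for by
#' oversampling of a behavior (no row or column dominates element-wise).
#' `D` always lies in `[-1, 1]`.
#'
#' @param P A [partner_dist()], a length-4 numeric vector in canonical type
#'   order, or a data frame with columns `p_pc`, `p_pd`, `p_tc`, `p_td`
#'   (vectorised over rows).
#' @return A numeric vector of index values in `[-1, 1]`.
#' @examples
#' discrimination_index(partner_dist(0.5, 0, 0.5, 0))  #  1: by behavior
#' discrimination_index(partner_dist(0.5, 0.5, 0, 0))  # -1: by color
#' @export
discrimination_index <- function(P) {
  if (is.data.frame(P)) {
    stopifnot(all(dist_names %in% names(P)))
    return(d_index_num(P$p_pc, P$p_pd, P$p_tc, P$p_td))
  }
  P <- as_partner_dist(P)
  d_index_num(P[["p_pc"]], P[["p_pd"]], P[["p_tc"]], P[["p_td"]])
}

check_records <- function(records) {
  needed <- c("episode", "race", "partner_id", "partner_color",
              "partner_strategy")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("episode records are missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(records)
}

#' Association tally from episode records
#'
#' Counts, per race index, how often the focal's partner was of each of the
#' four types, aggregated across episodes. Races in which the focal had no
#' partner (`partner_id` missing) are excluded from that race's counts.
#'
#' @param records A tibble of per-race episode records as produced by
#'   [run_episodes()].
#' @return A tibble with columns `race`, `type` (a factor over the four
#'   canonical partner types) and `n`.
#' @export
tally_associations <- function(records) {
  check_records(records)
  records |>
    dplyr::filter(!is.na(.data$partner_id)) |>
    dplyr::mutate(type = factor(
      paste(.data$partner_color, .data$partner_strategy, sep = "_"),
      levels = type_levels)) |>
    dplyr::count(.data$race, .data$type, .drop = FALSE)
}

#' Per-race association proportions
#'
#' Converts an episode-record tibble into per-race association distributions
#' (the empirical `P(i)`), in wide form.
#'
#' @inheritParams tally_associations
#' @return A tibble with columns `race`, `p_pc`, `p_pd`, `p_tc`, `p_td`,
#'   `n_episodes` (episodes contributing a partner at that race).
#' @export
association_proportions <- function(records) {
  tal <- tally_associations(records)
  wide <- tal |>
    dplyr::group_by(.data$race) |>
    dplyr::mutate(n_episodes = sum(.data$n), p = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(slot = dist_names[as.integer(.data$type)]) |>
    dplyr::select("race", "slot", "p", "n_episodes") |>
    tidyr::pivot_wider(names_from = "slot", values_from = "p")
  dplyr::select(wide, "race", dplyr::all_of(dist_names), "n_episodes")
}

#' Per-race discrimination index with bootstrap confidence intervals
#'
#' The point estimate at each race index is the discrimination index of the
#' pooled association proportions across episodes. Uncertainty is assessed by
#' resampling whole episodes with replacement (`n_boot` resamples) and
#' recomputing the pooled per-race index; a percentile interval at the given
#' level is reported. The same episode resamples are used at every race
#' index, preserving the within-episode dependence structure.
#'
#' @inheritParams tally_associations
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed for the resampling (the caller's RNG
#'   state is untouched).
#' @return A tibble of class `discrimination_trace` with columns `race`, `d`,
#'   `ci_low`, `ci_high`, `n_episodes`.
#' @export
discrimination_trace <- function(records, n_boot = 5000, level = 0.95,
                                 seed = NULL) {
  check_records(records)
  n_boot <- check_count(n_boot, "n_boot", min = 1L)
  check_prob(level, "level")
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  local_seed_if(seed)

  eps <- sort(unique(records$episode))
  E <- length(eps)
  if (E < 2L) stop("need at least 2 episodes to bootstrap", call. = FALSE)
  races <- sort(unique(records$race))
  rec <- records |>
    dplyr::filter(!is.na(.data$partner_id)) |>
    dplyr::mutate(
      ei = match(.data$episode, eps),
      ti = match(paste(.data$partner_color, .data$partner_strategy, sep = "_"),
                 type_levels))

  # episode-resampling weights shared across race indices
  W <- stats::rmultinom(n_boot, E, rep(1 / E, E)) # E x n_boot
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)

  rows <- lapply(races, function(r) {
    rr <- rec[rec$race == r, ]
    M <- matrix(0, nrow = E, ncol = 4L)
    M[cbind(rr$ei, rr$ti)] <- 1 # one partner per episode per race
    pooled <- colSums(M) / sum(M)
    cnt <- crossprod(M, W)                    # 4 x n_boot
    tot <- colSums(cnt)
    pr <- sweep(cnt, 2, pmax(tot, 1), "/")
    dstar <- d_index_num(pr[1, ], pr[2, ], pr[3, ], pr[4, ])
    ci <- stats::quantile(dstar[tot > 0], probs, names = FALSE)
    tibble::tibble(race = r,
                   d = d_index_num(pooled[1], pooled[2], pooled[3], pooled[4]),
                   ci_low = ci[1], ci_high = ci[2],
                   n_episodes = sum(M))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("discrimination_trace", class(out))
  out
}

#' Empirical awareness and stickiness from episode records
#'
#' Awareness is estimated as the proportion of races (with a partner) in
#' which the focal's partner was a cooperator. Stickiness is the proportion
#' of consecutive race pairs, both with a partner, in which the partner was
#' the same individual as in the immediately preceding race. Both estimators
#' are unconditional, matching how behavior is measured from observed
#' episodes; note that under uniform random choice among `k` coplayers the
#' expected stickiness is `1/k`.
#'
#' @inheritParams tally_associations
#' @return A one-row tibble with columns `awareness_hat`, `stickiness_hat`,
#'   `n_races` (races with a partner), `n_pairs` (consecutive partnered race
#'   pairs).
#' @export
empirical_behavior <- function(records) {
  check_records(records)
  if (nrow(records) == 0L) {
    stop("cannot estimate behavior from empty episode records", call. = FALSE)
  }
  dat <- records |>
    dplyr::arrange(.data$episode, .data$race) |>
    dplyr::group_by(.data$episode) |>
    dplyr::mutate(prev_id = dplyr::lag(.data$partner_id)) |>
    dplyr::ungroup()
  with_partner <- !is.na(dat$partner_id)
  coop <- dat$partner_strategy == "cooperator"
  pair_ok <- with_partner & !is.na(dat$prev_id)
  tibble::tibble(
    awareness_hat = mean(coop[with_partner]),
    stickiness_hat = if (any(pair_ok)) {
      mean(dat$partner_id[pair_ok] == dat$prev_id[pair_ok])
    } else NA_real_,
    n_races = sum(with_partner),
    n_pairs = sum(pair_ok)
  )
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the input values with replacement `n_boot` times, computes the
#' mean of each resample, and returns the percentile interval at the given
#' level. Deterministic given `seed`.
#'
#' @param x A numeric vector (e.g. per-episode discrimination index values),
#'   length >= 2.
#' @param n_boot Number of resamples (default 5000).
#' @param level Confidence level in (0, 1) (default 0.95).
#' @param seed Optional integer seed.
#' @return A one-row tibble with columns `low`, `high`.
#' @examples
#' bootstrap_ci(c(-1, 1, 0, 0.5, -0.5), n_boot = 1000, seed = 1)
#' @export
bootstrap_ci <- function(x, n_boot = 5000, level = 0.95, seed = NULL) {
  if (!is.numeric(x) || length(x) < 2L || anyNA(x)) {
    stop("`x` must be a numeric vector of length >= 2 without missing values",
         call. = FALSE)
  }
  n_boot <- check_count(n_boot, "n_boot", min = 1L)
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("`level` must be in (0, 1)", call. = FALSE)
  }
  local_seed_if(seed)
  n <- length(x)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  means <- colMeans(matrix(x[idx], nrow = n))
  qs <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  tibble::tibble(low = qs[1], high = qs[2])
}
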