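# Monte-Carlo simulator of the iterated partner-choice protocol:
# free mixing -> partner choice -> interaction -> outcome, repeated for
# n_races races per episode. Coplayers play unconditional strategies; the
# focal always cooperates (the Stag hunt best response to a chosen
# cooperator; the object of study is partner choice, not the rowing policy),
# so the focal payoff is R against a cooperator and S against a defector.

# Decision cascade on an index representation of the roster. Flags (the
# perceptual intervention) and awareness only operate once an interaction
# has been observed (first_race = FALSE).
choose_idx <- function(colors, cooperates, focal, prev_idx, prev_coop,
                       q, first_race) {
  if (!first_race) {
    if (!is.na(prev_idx) && prev_coop && stats::runif(1) < focal$s) {
      return(prev_idx)
    }
    if (q > 0 && stats::runif(1) < q) {
      cand <- which(cooperates) # honest signal: flags mark last-race cooperators
      if (length(cand)) return(cand[sample.int(length(cand), 1L)])
    }
    if (focal$omega > 0 && stats::runif(1) < focal$omega) {
      cand <- which(cooperates)
      if (length(cand)) return(cand[sample.int(length(cand), 1L)])
    }
  }
  want_purple <- stats::runif(1) < focal$b
  cand <- which(colors == (if (want_purple) "purple" else "teal"))
  if (!length(cand)) cand <- seq_along(colors) # fallback to the other color
  cand[sample.int(length(cand), 1L)]
}

#' One partner-choice decision of the focal agent
#'
#' Applies the focal decision cascade to a roster of coplayers: (1) if the
#' previous partner cooperated, re-pair with probability `s`; (2) otherwise,
#' if an intervention is active, follow the cooperator flags with probability
#' `q(beta)`; (3) otherwise, with probability `omega`, pick uniformly among
#' known cooperators; (4) otherwise pick a color by bias `b` (falling back to
#' the other color if no coplayer of the preferred color exists) and a
#' uniform coplayer of that color. Steps 1-3 are skipped on the first race of
#' an episode, before any interaction has been observed.
#'
#' @param coplayers A roster tibble (columns `id`, `color`, `strategy`).
#' @param focal A [focal_params()].
#' @param prev_partner Id of the previous partner, or `NULL`/`NA`.
#' @param prev_cooperated Did the previous partner cooperate?
#' @param intervention An [intervention_spec()] or `NULL`.
#' @param first_race Is this the first race of the episode?
#' @return The chosen coplayer as a one-row tibble.
#' @export
focal_choose <- function(coplayers, focal, prev_partner = NULL,
                         prev_cooperated = FALSE, intervention = NULL,
                         first_race = FALSE) {
  stopifnot(inherits(focal, "focal_params"))
  if (nrow(coplayers) == 0L) stop("empty coplayer roster", call. = FALSE)
  prev_idx <- if (is.null(prev_partner) || is.na(prev_partner)) NA_integer_
              else match(prev_partner, coplayers$id)
  q <- if (is.null(intervention)) 0 else intervention$availability
  i <- choose_idx(coplayers$color, coplayers$strategy == "cooperator",
                  focal, prev_idx, isTRUE(prev_cooperated), q, first_race)
  coplayers[i, ]
}

records_tibble <- function(episode, race, id, color, coop, repaired, payoff) {
  tibble::tibble(
    episode = as.integer(episode),
    race = as.integer(race),
    partner_id = id,
    partner_color = color,
    partner_strategy = ifelse(coop, "cooperator", "defector"),
    partner_cooperated = coop,
    repaired = repaired,
    focal_payoff = payoff
  )
}

run_finite <- function(n_episodes, focal, community, n_coplayers, n_races,
                       payoffs, intervention, policy, root_seed) {
  csize <- nrow(community)
  if (n_coplayers > csize) {
    stop("`n_coplayers` exceeds the community size", call. = FALSE)
  }
  ids <- community$id
  colors <- community$color
  coop <- community$strategy == "cooperator"
  q <- if (is.null(intervention)) 0 else intervention$availability

  if (policy == "random") {
    # no sequential dependence: vectorise across episodes and races
    set.seed(root_seed)
    roster <- vapply(seq_len(n_episodes),
                     function(i) sample.int(csize, n_coplayers),
                     integer(n_coplayers)) # n_coplayers x n_episodes
    pick <- matrix(sample.int(n_coplayers, n_episodes * n_races,
                              replace = TRUE),
                   nrow = n_races) # races x episodes
    comm_row <- roster[cbind(as.vector(pick),
                             rep(seq_len(n_episodes), each = n_races))]
    rep_flag <- rbind(FALSE, pick[-1L, , drop = FALSE] ==
                               pick[-n_races, , drop = FALSE])
    pc <- coop[comm_row]
    return(records_tibble(
      episode = rep(seq_len(n_episodes), each = n_races),
      race = rep.int(0:(n_races - 1L), n_episodes),
      id = ids[comm_row], color = colors[comm_row], coop = pc,
      repaired = as.vector(rep_flag),
      payoff = ifelse(pc, payoffs$R, payoffs$S)))
  }

  # parametric policy: sequential within an episode; per-episode child seeds
  seeds <- child_seeds(root_seed, n_episodes)
  n <- n_episodes * n_races
  o_ep <- integer(n); o_race <- integer(n); o_row <- integer(n)
  o_rep <- logical(n)
  pos <- 0L
  for (ep in seq_len(n_episodes)) {
    set.seed(seeds[ep])
    ro <- sample.int(csize, n_coplayers)
    rcol <- colors[ro]; rcoop <- coop[ro]
    prev <- NA_integer_
    for (r in seq_len(n_races)) {
      i <- choose_idx(rcol, rcoop, focal, prev,
                      !is.na(prev) && rcoop[prev], q, first_race = r == 1L)
      pos <- pos + 1L
      o_ep[pos] <- ep; o_race[pos] <- r - 1L; o_row[pos] <- ro[i]
      o_rep[pos] <- !is.na(prev) && i == prev
      prev <- i
    }
  }
  pc <- coop[o_row]
  records_tibble(o_ep, o_race, ids[o_row], colors[o_row], pc, o_rep,
                 ifelse(pc, payoffs$R, payoffs$S))
}

run_infinite <- function(n_episodes, focal, pop, n_races, payoffs,
                         intervention, root_seed) {
  set.seed(root_seed)
  P0 <- unclass(initial_distribution(focal, pop))
  z <- pop$rho + pop$tau
  Cvec <- if (z > 0) c(pop$rho / z, 0, pop$tau / z, 0) else rep(0, 4)
  # once cooperators exist, intervention flags identify them perfectly, so
  # the two information channels collapse into the effective awareness
  om <- if (z > 0) effective_awareness(focal$omega, intervention) else 0

  n <- n_episodes
  type <- matrix(0L, nrow = n, ncol = n_races)
  idn <- matrix(1L, nrow = n, ncol = n_races)
  stickm <- matrix(FALSE, nrow = n, ncol = n_races)
  type[, 1L] <- sample.int(4L, n, replace = TRUE, prob = P0)
  for (j in seq_len(n_races - 1L) + 1L) {
    prevt <- type[, j - 1L]
    prev_coop <- prevt == 1L | prevt == 3L
    stick <- prev_coop & stats::runif(n) < focal$s
    aware <- stats::runif(n) < om
    newt <- integer(n)
    ia <- which(!stick & aware)
    if (length(ia)) {
      newt[ia] <- sample.int(4L, length(ia), replace = TRUE, prob = Cvec)
    }
    ib <- which(!stick & !aware)
    if (length(ib)) {
      purple <- stats::runif(length(ib)) < focal$b
      coopp <- stats::runif(length(ib)) <
        ifelse(purple, pop$rho, pop$tau)
      newt[ib] <- 1L + as.integer(!coopp) + 2L * as.integer(!purple)
    }
    type[, j] <- ifelse(stick, prevt, newt)
    idn[, j] <- idn[, j - 1L] + as.integer(!stick)
    stickm[, j] <- stick
  }
  tl <- as.vector(t(type)) # race fastest within episode
  pc <- tl == 1L | tl == 3L
  records_tibble(
    episode = rep(seq_len(n), each = n_races),
    race = rep.int(0:(n_races - 1L), n),
    id = paste0("v", as.vector(t(idn))),
    color = c("purple", "purple", "teal", "teal")[tl],
    coop = pc,
    repaired = as.vector(t(stickm)),
    payoff = ifelse(pc, payoffs$R, payoffs$S)
  )
}

#' Simulate partner-choice episodes
#'
#' Runs `n_episodes` episodes of `n_races` races each and returns one row
#' per (episode, race) with the focal's partner, a re-pair flag and the
#' focal's Stag hunt payoff (the focal always cooperates; coplayers play
#' unconditional strategies).
#'
#' Two population modes are available. In `"finite"` mode, `n_coplayers`
#' agents are sampled from `community` for each episode and the focal
#' chooses among them via [focal_choose()]. In `"infinite"` mode the
#' partner's type is drawn directly from the analytical choice
#' distributions (each new partner is a fresh individual), which makes the
#' per-race association frequencies converge to [trajectory()] — the
#' simulator's analytic oracle.
#'
#' With `policy = "random"` the focal ignores its parameters and picks
#' uniformly among the coplayers every race (the random-baseline
#' calibration).
#'
#' @param n_episodes Number of episodes.
#' @param focal A [focal_params()] (ignored under the random policy).
#' @param community Roster tibble from [make_community()] (finite mode).
#' @param pop A [population_params()] (infinite mode).
#' @param n_coplayers Coplayers sampled per episode (default 5, so 6 players
#'   including the focal; `n_coplayers + 1` must be even so that everyone
#'   can pair).
#' @param n_races Races per episode (default 8).
#' @param payoffs A [stag_hunt_payoffs()].
#' @param intervention An [intervention_spec()] or `NULL`.
#' @param mode `"finite"` or `"infinite"`.
#' @param policy `"parametric"` or `"random"`.
#' @param seed Optional integer seed; identical seeds give identical
#'   records. In finite parametric mode, per-episode child seeds are spawned
#'   from it so earlier episodes are unchanged when `n_episodes` grows.
#' @return A tibble with columns `episode`, `race` (0-based), `partner_id`,
#'   `partner_color`, `partner_strategy`, `partner_cooperated`, `repaired`,
#'   `focal_payoff`.
#' @examples
#' comm <- make_community(12, training_bias = 0.5)
#' run_episodes(3, focal_params(0.5, 0.5, 0.5), community = comm, seed = 1)
#' @export
run_episodes <- function(n_episodes, focal = focal_params(),
                         community = NULL, pop = NULL,
                         n_coplayers = 5, n_races = 8,
                         payoffs = stag_hunt_payoffs(),
                         intervention = NULL,
                         mode = c("finite", "infinite"),
                         policy = c("parametric", "random"),
                         seed = NULL) {
  mode <- match.arg(mode)
  policy <- match.arg(policy)
  n_episodes <- check_count(n_episodes, "n_episodes", min = 1L)
  n_races <- check_count(n_races, "n_races", min = 1L)
  n_coplayers <- check_count(n_coplayers, "n_coplayers", min = 1L)
  if ((n_coplayers + 1L) %% 2L != 0L) {
    stop("`n_coplayers` + 1 must be even so all players can pair",
         call. = FALSE)
  }
  stopifnot(inherits(focal, "focal_params"),
            inherits(payoffs, "stag_hunt_payoffs"))
  if (!is.null(intervention)) stopifnot(inherits(intervention, "intervention_spec"))

  withr::local_preserve_seed()
  root_seed <- if (is.null(seed)) sample.int(2147483646L, 1L) else
    as.integer(seed)

  if (mode == "infinite") {
    if (is.null(pop)) stop("infinite mode needs `pop`", call. = FALSE)
    stopifnot(inherits(pop, "population_params"))
    if (policy == "random") {
      stop("the random policy is a finite-roster baseline", call. = FALSE)
    }
    run_infinite(n_episodes, focal, pop, n_races, payoffs, intervention,
                 root_seed)
  } else {
    if (is.null(community)) stop("finite mode needs `community`", call. = FALSE)
    run_finite(n_episodes, focal, community, n_coplayers, n_races, payoffs,
               intervention, policy, root_seed)
  }
}

#' @rdname run_episodes
#' @export
run_episode <- function(focal = focal_params(), community = NULL, pop = NULL,
                        ..., seed = NULL) {
  run_episodes(1L, focal = focal, community = community, pop = pop, ...,
               seed = seed)
}
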