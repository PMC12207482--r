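# The agent-based simulator: rosters, the focal decision cascade, episode
# records, the intervention, and agreement with the analytic oracle.

test_that("community rosters realise the requested color-strategy correlation", {
  c1 <- make_community(4, training_bias = 1)
  expect_equal(table(c1$color, c1$strategy)["purple", "cooperator"], 2)
  expect_equal(table(c1$color, c1$strategy)["teal", "defector"], 2)

  c0 <- make_community(8, training_bias = 0)
  expect_equal(unname(as.vector(table(c0$color, c0$strategy))), rep(2L, 4))

  ch <- make_community(8, training_bias = 0.5) # rho = 0.75, tau = 0.25
  tab <- table(ch$color, ch$strategy)
  expect_equal(unname(tab["purple", "cooperator"]), 3L)
  expect_equal(unname(tab["teal", "cooperator"]), 1L)
  expect_equal(sum(ch$strategy == "cooperator"), 4L) # half/half marginal
  expect_false(anyDuplicated(ch$id) > 0)

  pop <- community_population(ch)
  expect_equal(pop$rho, 0.75)
  expect_equal(pop$tau, 0.25)
  expect_error(make_community(7), "even")
})

test_that("the focal decision cascade honours its contracts", {
  roster <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    color = c("purple", "purple", "teal", "teal"),
    strategy = c("cooperator", "defector", "defector", "defector"))
  # s = 1 with a cooperating previous partner: always re-pair
  withr::with_seed(1, {
    for (i in 1:10) {
      ch <- focal_choose(roster, focal_params(omega = 0, s = 1, b = 0.5),
                         prev_partner = "c", prev_cooperated = TRUE)
      expect_equal(ch$id, "c")
    }
  })
  # omega = 1 with a single cooperator: always that cooperator
  withr::with_seed(2, {
    for (i in 1:10) {
      ch <- focal_choose(roster, focal_params(omega = 1, s = 0, b = 0.1))
      expect_equal(ch$id, "a")
    }
  })
  # all-teal roster with b = 1: fallback to the other color
  teal <- roster[roster$color == "teal", ]
  withr::with_seed(3, {
    ids <- replicate(20, focal_choose(
      teal, focal_params(omega = 0, s = 0, b = 1))$id)
    expect_true(all(ids %in% c("c", "d")))
    expect_equal(sort(unique(ids)), c("c", "d"))
  })
  expect_error(focal_choose(roster[0, ], focal_params()), "empty")
})

test_that("episode records account payoffs per the Stag hunt cells", {
  allc <- make_community(8, rho = 1, tau = 1)
  pay <- stag_hunt_payoffs(R = 5, T = 4, P = 2, S = 0)
  rec <- run_episodes(5, focal_params(0.2, 0.8, 0.5), community = allc,
                      payoffs = pay, seed = 1)
  expect_true(all(rec$focal_payoff == 5)) # cooperating focal, all cooperators
  mixed <- make_community(8, training_bias = 0)
  rec2 <- run_episodes(20, focal_params(0.3, 0.3, 0.3), community = mixed,
                       payoffs = pay, seed = 2)
  expect_true(all(rec2$focal_payoff == ifelse(rec2$partner_cooperated, 5, 0)))
  # partner fields are consistent with the roster
  key <- paste(mixed$color, mixed$strategy, sep = "|")
  names(key) <- mixed$id
  expect_identical(paste(rec2$partner_color, rec2$partner_strategy, sep = "|"),
                   unname(key[rec2$partner_id]))
})

test_that("identical seeds reproduce identical episode records in every mode", {
  comm <- make_community(12, training_bias = 0.5)
  pop <- population_params(0.75, 0.25)
  a1 <- run_episodes(30, focal_params(0.4, 0.6, 0.7), community = comm, seed = 9)
  a2 <- run_episodes(30, focal_params(0.4, 0.6, 0.7), community = comm, seed = 9)
  expect_identical(a1, a2)
  b1 <- run_episodes(30, community = comm, policy = "random", seed = 9)
  b2 <- run_episodes(30, community = comm, policy = "random", seed = 9)
  expect_identical(b1, b2)
  c1 <- run_episodes(30, focal_params(0.4, 0.6, 0.7), pop = pop,
                     mode = "infinite", seed = 9)
  c2 <- run_episodes(30, focal_params(0.4, 0.6, 0.7), pop = pop,
                     mode = "infinite", seed = 9)
  expect_identical(c1, c2)
})

test_that("growing the episode count leaves earlier parametric episodes unchanged", {
  comm <- make_community(12, training_bias = 0.5)
  small <- run_episodes(10, focal_params(0.4, 0.6, 0.7), community = comm,
                        seed = 5)
  big <- run_episodes(25, focal_params(0.4, 0.6, 0.7), community = comm,
                      seed = 5)
  expect_identical(small, big[big$episode <= 10, ])
})

test_that("infinite-mode frequencies track the analytic trajectory", {
  focal <- focal_params(0.5, 0.5, 0.5)
  pop <- population_params(0.75, 0.25)
  n <- 40000
  rec <- run_episodes(n, focal, pop = pop, mode = "infinite", n_races = 4,
                      seed = TEST_SEED)
  props <- association_proportions(rec)
  tr <- trajectory(focal, pop, n_iters = 3)
  for (r in 0:3) {
    p_hat <- unlist(props[props$race == r, c("p_pc", "p_pd", "p_tc", "p_td")])
    p_exp <- unlist(tr[r + 1, c("p_pc", "p_pd", "p_tc", "p_td")])
    se <- sqrt(p_exp * (1 - p_exp) / n)
    expect_true(all(abs(p_hat - p_exp) <= pmax(3 * se, 1e-12)),
                info = sprintf("race %d", r))
  }
})

test_that("effective awareness composes the intervention channel", {
  expect_equal(effective_awareness(0.3, NULL), 0.3)
  expect_equal(effective_awareness(0.3, intervention_spec(beta = 0)), 1)
  expect_equal(effective_awareness(0.3, intervention_spec(beta = 0.02)), 0.3)
  expect_equal(effective_awareness(0.4, intervention_spec(beta = 0.005)), 0.7)
  q <- intervention_availability(c(0, 0.002, 0.005, 0.02, 1))
  expect_equal(q, c(1, 0.75, 0.5, 0, 0))
  expect_true(all(diff(intervention_availability(seq(0, 0.03, by = 0.001))) <= 0))
})

test_that("the intervention leaves the first race untouched", {
  comm <- make_community(20, training_bias = 0)
  focal <- focal_params(omega = 0.2, s = 0.5, b = 0.8)
  plain <- run_episodes(400, focal, community = comm, seed = 11)
  boosted <- run_episodes(400, focal, community = comm,
                          intervention = intervention_spec(beta = 0),
                          seed = 11)
  r0p <- plain[plain$race == 0, ]
  r0b <- boosted[boosted$race == 0, ]
  # same seed protocol: the race-0 choice path consumes identical draws
  expect_identical(r0p$partner_id, r0b$partner_id)
  # from race 1 on, q = 1 finds a cooperator whenever the sampled roster has
  # one (an all-defector roster leaves no cooperator to flag in any race)
  by_ep <- split(boosted, boosted$episode)
  ok <- vapply(by_ep, function(e) {
    all(e$partner_cooperated[e$race > 0]) || !any(e$partner_cooperated)
  }, logical(1))
  expect_true(all(ok))
  expect_gt(mean(boosted$partner_cooperated[boosted$race > 0]), 0.9)
})

test_that("finite-mode estimators recover extreme generating parameters", {
  # omega = 1: every post-first-race partner is a cooperator (community with
  # only 2 defectors, so no 5-player roster can lack cooperators)
  comm <- make_community(20, rho = 0.9, tau = 0.9)
  rec <- run_episodes(400, focal_params(omega = 1, s = 0, b = 0.5),
                      community = comm, seed = 21)
  aware_late <- empirical_behavior(rec[rec$race > 0, ])
  expect_equal(aware_late$awareness_hat, 1)
  beh <- empirical_behavior(rec)
  # race 0 is chosen by color alone: expected awareness (gamma0_hat + 7)/8
  expect_lt(abs(beh$awareness_hat - (0.9 + 7) / 8),
            3 * sqrt(0.9 * 0.1 / 400) / 8)
  # s recovery in infinite mode against always-cooperating partners: a fresh
  # individual is drawn whenever the stick fails, so stickiness_hat -> s
  s <- 0.8
  rec2 <- run_episodes(5000, focal_params(omega = 0, s = s, b = 0.5),
                       pop = population_params(1, 1), mode = "infinite",
                       seed = 22)
  beh2 <- empirical_behavior(rec2)
  se <- sqrt(s * (1 - s) / beh2$n_pairs)
  expect_lt(abs(beh2$stickiness_hat - s), 3 * se)
})

test_that("episode shape is validated", {
  comm <- make_community(8)
  expect_error(run_episodes(2, community = comm, n_coplayers = 4), "even")
  expect_error(run_episodes(2, pop = population_params(), mode = "finite"),
               "community")
  expect_error(run_episodes(2, community = comm, mode = "infinite"), "pop")
  expect_error(run_episodes(2, community = comm, n_coplayers = 9),
               "community size")
})
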