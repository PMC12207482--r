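# The analytical recursion: choice distributions, the step, the trajectory,
# and the closed-form cooperator-pairing probability.

test_that("initial distribution follows the color-bias form", {
  expect_equal(
    unclass(initial_distribution(focal_params(b = 0.5),
                                 population_params(0.5, 0.5))),
    c(p_pc = 0.25, p_pd = 0.25, p_tc = 0.25, p_td = 0.25))
  expect_equal(
    unclass(initial_distribution(focal_params(b = 1),
                                 population_params(0.5, 0.5))),
    c(p_pc = 0.5, p_pd = 0.5, p_tc = 0, p_td = 0))
  expect_equal(
    unclass(initial_distribution(focal_params(b = 0.5), anchor_pop())),
    c(p_pc = 0.375, p_pd = 0.125, p_tc = 0.125, p_td = 0.375))
})

test_that("cooperator color distribution splits by cooperation prevalence", {
  expect_equal(
    unclass(cooperator_color_distribution(population_params(0.5, 0.5))),
    c(p_pc = 0.5, p_pd = 0, p_tc = 0.5, p_td = 0))
  expect_equal(
    unclass(cooperator_color_distribution(population_params(1, 0))),
    c(p_pc = 1, p_pd = 0, p_tc = 0, p_td = 0))
  expect_equal(
    unclass(cooperator_color_distribution(anchor_pop())),
    c(p_pc = 0.75, p_pd = 0, p_tc = 0.25, p_td = 0))
  expect_error(cooperator_color_distribution(population_params(0, 0)),
               "no cooperators")
})

test_that("new-partner distribution is the awareness convex combination", {
  pop <- anchor_pop()
  expect_equal(new_partner_distribution(focal_params(omega = 0, b = 0.3), pop),
               initial_distribution(focal_params(b = 0.3), pop))
  expect_equal(new_partner_distribution(focal_params(omega = 1), pop),
               cooperator_color_distribution(pop))
  expect_equal(
    unclass(new_partner_distribution(focal_params(omega = 0.5, b = 0.5), pop)),
    c(p_pc = 0.5625, p_pd = 0.0625, p_tc = 0.1875, p_td = 0.1875))
})

test_that("conditioning on cooperators normalises the cooperator mass", {
  expect_equal(cooperator_conditional(partner_dist(0.5, 0, 0.5, 0)),
               partner_dist(0.5, 0, 0.5, 0))
  expect_equal(
    unclass(cooperator_conditional(partner_dist(0.375, 0.125, 0.125, 0.375))),
    c(p_pc = 0.75, p_pd = 0, p_tc = 0.25, p_td = 0))
  expect_error(cooperator_conditional(partner_dist(0, 0.5, 0, 0.5)),
               "no cooperator mass")
})

test_that("one recursion step matches the hand-computed anchor", {
  focal <- anchor_focal(); pop <- anchor_pop()
  P0 <- initial_distribution(focal, pop)
  P1 <- step_distribution(P0, focal, pop)
  expect_equal(unclass(P1),
               c(p_pc = 0.609375, p_pd = 0.046875,
                 p_tc = 0.203125, p_td = 0.140625))
  # s = 0: the step always returns nu
  f0 <- focal_params(omega = 0.5, s = 0, b = 0.5)
  expect_equal(step_distribution(partner_dist(0, 0.5, 0, 0.5), f0, pop),
               new_partner_distribution(f0, pop))
  # omega = 0, s = 0: P(0) is a fixed point
  ff <- focal_params(omega = 0, s = 0, b = 0.7)
  expect_equal(step_distribution(initial_distribution(ff, pop), ff, pop),
               initial_distribution(ff, pop))
})

test_that("a zero-cooperator-mass state steps to nu without evaluating g", {
  focal <- focal_params(omega = 0.3, s = 0.9, b = 0.2)
  pop <- anchor_pop()
  expect_equal(step_distribution(partner_dist(0, 0.6, 0, 0.4), focal, pop),
               new_partner_distribution(focal, pop))
})

test_that("trajectory iterates the step and carries gamma and D", {
  focal <- anchor_focal(); pop <- anchor_pop()
  tr <- trajectory(focal, pop, n_iters = 8)
  expect_s3_class(tr, "partner_trajectory")
  expect_equal(nrow(tr), 9L)
  expect_equal(unlist(tr[1, c("p_pc", "p_pd", "p_tc", "p_td")]),
               unclass(initial_distribution(focal, pop)))
  # every row reproduces an explicit step_distribution chain
  P <- initial_distribution(focal, pop)
  for (i in 2:9) {
    P <- step_distribution(P, focal, pop)
    expect_equal(unlist(tr[i, c("p_pc", "p_pd", "p_tc", "p_td")]),
                 unclass(P))
  }
  expect_equal(tr$d[2], 0.125) # hand-evaluated on the step anchor
  expect_equal(nrow(trajectory(focal, pop, n_iters = 0)), 1L)
})

test_that("full awareness removes defector mass from iteration 1 onward", {
  tr <- trajectory(focal_params(omega = 1, s = 0.4, b = 0.8),
                   population_params(0.6, 0.3), n_iters = 6)
  expect_true(all(tr$p_pd[-1] == 0))
  expect_true(all(tr$p_td[-1] == 0))
})

test_that("closed-form gamma matches its anchors and the f = 1 limit", {
  focal <- anchor_focal()
  expect_equal(gamma_closed_form(focal, 0.5, 0), 0.5)
  expect_equal(gamma_closed_form(focal, 0.5, 1), 0.8125) # e=0.75, f=0.125
  expect_equal(gamma_closed_form(focal_params(omega = 1, s = 0.3), 0.2, 1:5),
               rep(1, 5))
  # f = 1 degenerate branch: s=1, omega=0, gamma0=0 stays at 0
  expect_equal(gamma_closed_form(focal_params(omega = 0, s = 1), 0, 0:4),
               rep(0, 5))
})

test_that("gamma limit matches the geometric fixed point", {
  expect_equal(gamma_limit(focal_params(omega = 1, s = 0.7), 0.3), 1)
  expect_equal(gamma_limit(focal_params(omega = 0, s = 0), 0.4), 0.4)
  expect_equal(gamma_limit(anchor_focal(), 0.5), 0.75 / 0.875)
  expect_error(gamma_limit(focal_params(omega = 0, s = 1), 0), "f = 1")
})

test_that("recursion and closed-form gamma agree over random parameters", {
  withr::local_seed(TEST_SEED)
  pars <- random_params(200)
  for (k in seq_len(nrow(pars))) {
    p <- pars[k, ]
    focal <- focal_params(p$omega, p$s, p$b)
    pop <- population_params(p$rho, p$tau)
    tr <- trajectory(focal, pop, n_iters = 16)
    expect_equal(tr$gamma, gamma_closed_form(focal, tr$gamma[1], 0:16),
                 tolerance = 1e-12)
  }
})

test_that("gamma contracts monotonically toward its limit at rate f", {
  withr::local_seed(TEST_SEED + 1L)
  pars <- random_params(100)
  for (k in seq_len(nrow(pars))) {
    p <- pars[k, ]
    focal <- focal_params(p$omega, p$s, p$b)
    pop <- population_params(p$rho, p$tau)
    tr <- trajectory(focal, pop, n_iters = 12)
    gp <- gamma_params(focal, tr$gamma[1])
    if (abs(1 - gp$f) < 1e-14) next
    lim <- gamma_limit(focal, tr$gamma[1])
    gaps <- abs(tr$gamma - lim)
    expect_true(all(gaps[-1] <= gp$f * gaps[-length(gaps)] + 1e-12))
  }
})

test_that("every returned distribution conserves probability", {
  withr::local_seed(TEST_SEED + 2L)
  pars <- random_params(100)
  for (k in seq_len(nrow(pars))) {
    p <- pars[k, ]
    tr <- trajectory(focal_params(p$omega, p$s, p$b),
                     population_params(p$rho, p$tau), n_iters = 10)
    mass <- tr$p_pc + tr$p_pd + tr$p_tc + tr$p_td
    expect_true(all(abs(mass - 1) <= 1e-12))
    expect_true(all(tr[c("p_pc", "p_pd", "p_tc", "p_td")] >= 0))
  }
})

test_that("the fixed point omega = s = 0 holds exactly", {
  focal <- focal_params(omega = 0, s = 0, b = 0.3)
  pop <- population_params(0.8, 0.1)
  tr <- trajectory(focal, pop, n_iters = 10)
  P0 <- unclass(initial_distribution(focal, pop))
  for (i in seq_len(nrow(tr))) {
    expect_identical(unname(unlist(tr[i, c("p_pc", "p_pd", "p_tc", "p_td")])),
                     unname(P0))
  }
})

test_that("color-swap symmetry: (rho<->tau, b<->1-b) permutes the output", {
  withr::local_seed(TEST_SEED + 3L)
  pars <- random_params(50)
  swap <- c("p_tc", "p_td", "p_pc", "p_pd")
  for (k in seq_len(nrow(pars))) {
    p <- pars[k, ]
    tr1 <- trajectory(focal_params(p$omega, p$s, p$b),
                      population_params(p$rho, p$tau), n_iters = 6)
    tr2 <- trajectory(focal_params(p$omega, p$s, 1 - p$b),
                      population_params(p$tau, p$rho), n_iters = 6)
    expect_equal(as.data.frame(tr1[c("p_pc", "p_pd", "p_tc", "p_td")]),
                 stats::setNames(as.data.frame(tr2[swap]),
                                 c("p_pc", "p_pd", "p_tc", "p_td")),
                 tolerance = 1e-12)
  }
})

test_that("distribution validation distinguishes noise from logic errors", {
  expect_error(partner_dist(0.5, 0.5, 0.5, -0.5), "\\[0, 1\\]")
  expect_error(as_partner_dist(c(0.3, 0.3, 0.3, 0.3)), "sum to 1")
  d <- as_partner_dist(c(1 + 1e-14, -1e-14, 0, 0))
  expect_identical(unname(d[["p_pd"]]), 0)
})

test_that("tidy and glance summarise the analytic model object", {
  m <- partner_model(anchor_focal(), anchor_pop(), n_races = 8)
  td <- tidy(m)
  expect_equal(nrow(td), 9L)
  gl <- glance(m)
  expect_equal(gl$gamma0, 0.5)
  expect_equal(gl$e, 0.75)
  expect_equal(gl$f, 0.125)
  expect_equal(gl$gamma_limit, 6 / 7)
  expect_equal(gl$d_last, td$d[9])
})
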