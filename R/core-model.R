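# The analytical model of iterated partner choice.
#
# One iteration: if the focal liked their previous partner (the partner
# cooperated) they re-pair with probability s; otherwise they draw a new
# partner -- a cooperator with probability omega (colors by prevalence of
# cooperation), else by color bias b. With unconditional coplayers this gives
# the affine recursion on the association distribution
#   P(i+1) = (1 - s*gamma(i)) * nu + s*gamma(i) * g(i),
# whose cooperator mass gamma(i) solves an affine, first-order, autonomous
# difference equation with a geometric closed form.

#' Association distribution on the first iteration
#'
#' On the first iteration nothing has been observed, so the focal chooses by
#' color bias alone: `P(0) = (b*rho, b*(1-rho), (1-b)*tau, (1-b)*(1-tau))`.
#'
#' @param focal A [focal_params()].
#' @param pop A [population_params()].
#' @return A [partner_dist()].
#' @examples
#' initial_distribution(focal_params(b = 0.5), population_params(0.75, 0.25))
#' @export
initial_distribution <- function(focal, pop) {
  stopifnot(inherits(focal, "focal_params"), inherits(pop, "population_params"))
  b <- focal$b
  new_partner_dist(c(b * pop$rho, b * (1 - pop$rho),
                     (1 - b) * pop$tau, (1 - b) * (1 - pop$tau)))
}

#' Color distribution of cooperators in the population
#'
#' When the focal succeeds in identifying a cooperator, the partner's color
#' depends only on the prevalence of cooperation by color:
#' `C = (rho/(rho+tau), 0, tau/(rho+tau), 0)` in canonical type order.
#'
#' @param pop A [population_params()] with `rho + tau > 0`.
#' @return A [partner_dist()] with mass only on cooperator types.
#' @export
cooperator_color_distribution <- function(pop) {
  stopifnot(inherits(pop, "population_params"))
  z <- pop$rho + pop$tau
  if (z <= 0) {
    stop("degenerate population: no cooperators exist (rho + tau = 0)",
         call. = FALSE)
  }
  new_partner_dist(c(pop$rho / z, 0, pop$tau / z, 0))
}

#' Distribution of newly chosen partners
#'
#' When forced to choose a new partner after the first iteration, the focal
#' picks a cooperator with probability `omega` (colors by `C`), otherwise
#' falls back on color bias (distribution `P(0)`):
#' `nu = omega * C + (1 - omega) * P(0)`.
#'
#' @inheritParams initial_distribution
#' @return A [partner_dist()].
#' @export
new_partner_distribution <- function(focal, pop) {
  P0 <- initial_distribution(focal, pop)
  if (focal$omega == 0) return(P0)
  Cd <- cooperator_color_distribution(pop)
  new_partner_dist(focal$omega * unclass(Cd) + (1 - focal$omega) * unclass(P0))
}

#' Color distribution of cooperator partners
#'
#' `g(i)` conditions an association distribution on the partner being a
#' cooperator: `g = (p_pc/gamma, 0, p_tc/gamma, 0)` with
#' `gamma = p_pc + p_tc`.
#'
#' @param P A [partner_dist()] with positive cooperator mass.
#' @return A [partner_dist()].
#' @export
cooperator_conditional <- function(P) {
  P <- as_partner_dist(P)
  gam <- gamma_of(P)
  if (gam <= 0) {
    stop("degenerate distribution: no cooperator mass (gamma = 0)", call. = FALSE)
  }
  new_partner_dist(c(P[["p_pc"]] / gam, 0, P[["p_tc"]] / gam, 0))
}

#' One iteration of the partner-choice recursion
#'
#' `P(i+1) = (1 - s*gamma(i)) * nu + s*gamma(i) * g(i)`. When `gamma(i) = 0`
#' the `g` term has coefficient zero (a removable singularity) and the step
#' returns `nu`.
#'
#' @param P The association distribution at the current iteration.
#' @inheritParams initial_distribution
#' @return The association distribution at the next iteration.
#' @export
step_distribution <- function(P, focal, pop) {
  P <- as_partner_dist(P)
  nu <- new_partner_distribution(focal, pop)
  gam <- gamma_of(P)
  w <- focal$s * gam
  if (w == 0) return(nu)
  g <- cooperator_conditional(P)
  new_partner_dist((1 - w) * unclass(nu) + w * unclass(g))
}

# Bare-vector recursion used by trajectories and sweeps: no class overhead.
# Returns an (n_iters + 1) x 4 matrix of P(0) .. P(n_iters).
p_recursion <- function(omega, s, b, rho, tau, n_iters) {
  P0 <- c(b * rho, b * (1 - rho), (1 - b) * tau, (1 - b) * (1 - tau))
  if (omega > 0 && rho + tau <= 0) {
    stop("degenerate population: no cooperators exist (rho + tau = 0)",
         call. = FALSE)
  }
  nu <- if (omega > 0) {
    z <- rho + tau
    omega * c(rho / z, 0, tau / z, 0) + (1 - omega) * P0
  } else {
    P0
  }
  out <- matrix(0, nrow = n_iters + 1L, ncol = 4L,
                dimnames = list(NULL, dist_names))
  out[1L, ] <- P <- P0
  for (i in seq_len(n_iters)) {
    gam <- P[1L] + P[3L]
    w <- s * gam
    P <- if (w == 0) nu else (1 - w) * nu + (w / gam) * c(P[1L], 0, P[3L], 0)
    out[i + 1L, ] <- P
  }
  out
}

#' Trajectory of the association distribution
#'
#' Iterates the recursion from `P(0)` and returns one row per iteration,
#' together with the cooperator-pairing probability `gamma` and the
#' discrimination index `d`.
#'
#' When an [intervention_spec()] is supplied, the perceptual signal raises the
#' effective awareness to `1 - (1 - omega)(1 - q(beta))` for every choice made
#' after the first interaction (iterations >= 1); iteration 0 is unaffected,
#' as the signal can only be triggered by an interaction.
#'
#' @inheritParams initial_distribution
#' @param n_iters Number of recursion steps (>= 0); the result has
#'   `n_iters + 1` rows for iterations `0..n_iters`.
#' @param intervention Optional [intervention_spec()].
#' @return A tibble of class `partner_trajectory` with columns `iteration`,
#'   `p_pc`, `p_pd`, `p_tc`, `p_td`, `gamma`, `d`.
#' @examples
#' trajectory(focal_params(0.5, 0.5, 0.5), population_params(0.75, 0.25), 8)
#' @export
trajectory <- function(focal, pop, n_iters = 8, intervention = NULL) {
  stopifnot(inherits(focal, "focal_params"), inherits(pop, "population_params"))
  n_iters <- check_count(n_iters, "n_iters", min = 0L)
  omega_eff <- effective_awareness(focal$omega, intervention)
  m0 <- p_recursion(focal$omega, focal$s, focal$b, pop$rho, pop$tau, 0L)
  m <- p_recursion(omega_eff, focal$s, focal$b, pop$rho, pop$tau, n_iters)
  m[1L, ] <- m0[1L, ] # iteration 0 predates any interaction
  out <- tibble::as_tibble(as.data.frame(m))
  out <- dplyr::mutate(out,
    iteration = 0:n_iters,
    gamma = .data$p_pc + .data$p_tc,
    d = discrimination_index(out),
    .before = 1
  )
  out <- dplyr::relocate(out, "iteration", dplyr::all_of(dist_names),
                         "gamma", "d")
  class(out) <- c("partner_trajectory", class(out))
  out
}

#' Affine-recursion parameters for the cooperator-pairing probability
#'
#' The cooperator mass `gamma(i)` satisfies
#' `gamma(i+1) = e + f * gamma(i)` with intercept
#' `e = 1 - (1 - omega)(1 - gamma0)` and rate
#' `f = s (1 - omega)(1 - gamma0)`, where `gamma0` is the cooperator mass at
#' iteration 0 (`b*rho + (1-b)*tau`).
#'
#' @param focal A [focal_params()].
#' @param gamma0 Cooperator-pairing probability at iteration 0.
#' @return An object of class `gamma_params` with fields `gamma0`, `e`, `f`.
#' @export
gamma_params <- function(focal, gamma0) {
  stopifnot(inherits(focal, "focal_params"))
  check_prob(gamma0, "gamma0")
  k <- (1 - focal$omega) * (1 - gamma0)
  structure(list(gamma0 = gamma0, e = 1 - k, f = focal$s * k),
            class = "gamma_params")
}

#' Closed form for the cooperator-pairing probability
#'
#' `gamma(i) = e * (1 - f^i)/(1 - f) + f^i * gamma0`, the solution of the
#' affine first-order recursion. When `f = 1` (possible only for `s = 1`,
#' `omega = 0`, `gamma0 = 0`) the continuity limit `e*i + gamma0` is used.
#'
#' @inheritParams gamma_params
#' @param i Iteration index (vectorised, nonnegative integers).
#' @return `gamma(i)`, a probability (vectorised over `i`).
#' @examples
#' gamma_closed_form(focal_params(0.5, 0.5, 0.5), gamma0 = 0.5, i = 0:8)
#' @export
gamma_closed_form <- function(focal, gamma0, i) {
  gp <- gamma_params(focal, gamma0)
  if (any(i < 0) || any(i != floor(i))) {
    stop("`i` must contain nonnegative integers", call. = FALSE)
  }
  if (abs(1 - gp$f) < 1e-14) {
    gp$e * i + gamma0
  } else {
    gp$e * (1 - gp$f^i) / (1 - gp$f) + gp$f^i * gamma0
  }
}

#' Limit of the cooperator-pairing probability
#'
#' `gamma(i)` converges geometrically (at rate `f`) from `gamma0` to
#' `e / (1 - f)`.
#'
#' @inheritParams gamma_params
#' @return The limit probability `e / (1 - f)`.
#' @export
gamma_limit <- function(focal, gamma0) {
  gp <- gamma_params(focal, gamma0)
  if (abs(1 - gp$f) < 1e-14) {
    stop("degenerate recursion: f = 1, gamma(i) has no finite-rate limit",
         call. = FALSE)
  }
  gp$e / (1 - gp$f)
}

#' Fit-free analytic partner-choice model object
#'
#' Bundles a focal/population parameterisation with its trajectory and the
#' gamma-recursion constants, for use with [generics::tidy()] (the per-
#' iteration trajectory) and [generics::glance()] (one-row summary).
#'
#' @inheritParams trajectory
#' @param n_races Number of races (iterations simulated after iteration 0).
#' @return An object of class `partner_model`.
#' @examples
#' m <- partner_model(focal_params(0.5, 0.5, 0.5), population_params(0.75, 0.25))
#' glance(m)
#' @export
partner_model <- function(focal, pop, n_races = 8, intervention = NULL) {
  traj <- trajectory(focal, pop, n_iters = n_races, intervention = intervention)
  gamma0 <- traj$gamma[1L]
  structure(
    list(focal = focal, pop = pop, intervention = intervention,
         trajectory = traj, gamma = gamma_params(focal, gamma0)),
    class = "partner_model"
  )
}

#' @export
print.partner_model <- function(x, ...) {
  cat(sprintf(
    "<partner_model> omega = %g, s = %g, b = %g | rho = %g, tau = %g | %d iterations\n",
    x$focal$omega, x$focal$s, x$focal$b, x$pop$rho, x$pop$tau,
    nrow(x$trajectory) - 1L))
  cat(sprintf("  gamma0 = %.4f, e = %.4f, f = %.4f, D(last) = %.4f\n",
              x$gamma$gamma0, x$gamma$e, x$gamma$f,
              x$trajectory$d[nrow(x$trajectory)]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn partner_model Per-iteration trajectory as a tibble.
#' @param x A `partner_model`.
#' @param ... Unused.
#' @method tidy partner_model
#' @export
tidy.partner_model <- function(x, ...) {
  out <- x$trajectory
  class(out) <- setdiff(class(out), "partner_trajectory")
  out
}

#' @describeIn partner_model One-row summary (gamma constants, limit, first
#'   and last discrimination index).
#' @method glance partner_model
#' @export
glance.partner_model <- function(x, ...) {
  n <- nrow(x$trajectory)
  tibble::tibble(
    gamma0 = x$gamma$gamma0,
    e = x$gamma$e,
    f = x$gamma$f,
    gamma_limit = if (abs(1 - x$gamma$f) < 1e-14) NA_real_ else
      x$gamma$e / (1 - x$gamma$f),
    d_first = x$trajectory$d[1L],
    d_last = x$trajectory$d[n],
    n_iters = n - 1L
  )
}
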