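#' Focal-agent parameters: awareness, stickiness and color bias
#'
#' The focal individual in the iterated partner-choice model is characterised
#' by three probabilities:
#' \describe{
#'   \item{`omega` (awareness)}{the probability that, when forced to choose a
#'     new partner, the focal identifies and pairs with a cooperator,
#'     regardless of color.}
#'   \item{`s` (stickiness)}{the probability that, if the focal liked their
#'     previous partner (the partner cooperated), they re-pair with them on
#'     the next iteration.}
#'   \item{`b` (bias)}{the probability of choosing a purple partner when both
#'     the stickiness and awareness channels fail (or on the first
#'     iteration).}
#' }
#'
#' @param omega,s,b Probabilities in `[0, 1]`.
#' @return An object of class `focal_params`.
#' @examples
#' focal_params(omega = 0.5, s = 0.5, b = 0.5)
#' @export
focal_params <- function(omega = 0.5, s = 0.5, b = 0.5) {
  structure(
    list(omega = check_prob(omega, "omega"),
         s     = check_prob(s, "s"),
         b     = check_prob(b, "b")),
    class = "focal_params"
  )
}

#' @export
print.focal_params <- function(x, ...) {
  cat(sprintf("<focal_params> awareness omega = %g, stickiness s = %g, bias b = %g\n",
              x$omega, x$s, x$b))
  invisible(x)
}

#' Population composition: cooperator proportions by color
#'
#' `rho` is the proportion of purple agents that cooperate and `tau` the
#' proportion of teal agents that cooperate. Operations that condition on
#' choosing a cooperator (the awareness channel) require `rho + tau > 0`.
#'
#' @param rho,tau Probabilities in `[0, 1]`.
#' @return An object of class `population_params`.
#' @seealso [population_from_bias()] to derive `(rho, tau)` from a
#'   color-strategy correlation.
#' @examples
#' population_params(rho = 0.75, tau = 0.25)
#' @export
population_params <- function(rho = 0.5, tau = 0.5) {
  structure(
    list(rho = check_prob(rho, "rho"), tau = check_prob(tau, "tau")),
    class = "population_params"
  )
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf("<population_params> rho = %g (purple cooperators), tau = %g (teal cooperators)\n",
              x$rho, x$tau))
  invisible(x)
}

#' Map a training bias (color-strategy correlation) to (rho, tau)
#'
#' A community with half its agents of each color and half of each strategy,
#' whose color-strategy correlation is `training_bias`, has purple cooperator
#' proportion `rho = (1 + training_bias)/2` and teal cooperator proportion
#' `tau = (1 - training_bias)/2`. This is the unique linear map preserving
#' the half/half marginals; `training_bias = 0` gives independence and
#' `training_bias = 1` perfect correlation.
#'
#' @param training_bias Correlation in `[0, 1]`.
#' @return A [population_params()] object.
#' @examples
#' population_from_bias(0.5) # rho = 0.75, tau = 0.25
#' @export
population_from_bias <- function(training_bias) {
  check_prob(training_bias, "training_bias")
  population_params(rho = (1 + training_bias) / 2,
                    tau = (1 - training_bias) / 2)
}

#' Stag hunt payoff matrix
#'
#' Row player's payoffs for the 2x2 Stag hunt: `R` for mutual cooperation,
#' `S` for cooperating against a defector, `T` for defecting against a
#' cooperator, `P` for mutual defection, with the ordering `R > T >= P > S`
#' (coordination beats the safe option, but cooperating alone is worst).
#' Payoff values do not enter the discrimination index; only the ordering is
#' constrained.
#'
#' @param R,T,P,S Payoff values satisfying `R > T >= P > S`.
#' @return An object of class `stag_hunt_payoffs`.
#' @examples
#' stag_hunt_payoffs()
#' @export
stag_hunt_payoffs <- function(R = 4, T = 3, P = 3, S = 1) {
  vals <- c(R = R, T = T, P = P, S = S)
  if (!is.numeric(vals) || anyNA(vals)) {
    stop("payoffs must be numeric", call. = FALSE)
  }
  if (!(R > T && T >= P && P > S)) {
    stop("Stag hunt payoffs must satisfy R > T >= P > S", call. = FALSE)
  }
  structure(as.list(vals), class = "stag_hunt_payoffs")
}

#' @export
print.stag_hunt_payoffs <- function(x, ...) {
  cat(sprintf("<stag_hunt_payoffs> R = %g, T = %g, P = %g, S = %g (R > T >= P > S)\n",
              x$R, x$T, x$P, x$S))
  invisible(x)
}
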