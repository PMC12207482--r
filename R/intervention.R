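# The perceptual intervention ("crown"): an honest signal flagging agents
# that cooperated during the last interaction, whose persistence into the
# next partner-choice phase is governed by a decay parameter beta.

# Anchor points for the decay -> availability mapping. beta = 0 keeps the
# signal until the next partner-choice phase (always available); larger betas
# make it vanish progressively earlier; at 0.02 it is gone before any choice.
beta_anchor <- data.frame(beta = c(0, 0.002, 0.005, 0.02),
                          q = c(1, 0.75, 0.5, 0))

#' Availability of the perceptual-intervention signal
#'
#' Maps the signal decay `beta` to the probability `q(beta)` that the flag
#' set during the last interaction is still visible at the next
#' partner-choice phase. The mapping is a monotone non-increasing
#' interpolation through `q(0) = 1`, `q(0.002) = 0.75`, `q(0.005) = 0.5`,
#' `q(0.02) = 0` (and 0 beyond); the exact temporal geometry of the decay is
#' environment-specific, so the mapping is configurable via
#' [intervention_spec()]'s `availability` argument.
#'
#' @param beta Nonnegative decay (vectorised).
#' @return Availability probabilities `q(beta)`.
#' @examples
#' intervention_availability(c(0, 0.002, 0.005, 0.02))
#' @export
intervention_availability <- function(beta) {
  if (!is.numeric(beta) || any(is.na(beta)) || any(beta < 0)) {
    stop("`beta` must be nonnegative", call. = FALSE)
  }
  stats::approx(beta_anchor$beta, beta_anchor$q, xout = pmin(beta, 0.02),
                method = "linear", rule = 2)$y
}

#' Perceptual-intervention specification
#'
#' Describes the exogenous signal that flags recent cooperators. `beta`
#' controls how quickly the flag decays; `availability` is the probability
#' that the flag survives to the next partner-choice phase (derived from
#' `beta` via [intervention_availability()] unless given explicitly).
#' Because the signal can only be triggered by an interaction, it has no
#' effect on the very first partner choice of an episode.
#'
#' @param beta Nonnegative decay parameter.
#' @param coop_threshold Fraction of cooperative actions during the last
#'   interaction required to earn the flag (default 0.75; trivially satisfied
#'   by unconditional cooperators).
#' @param availability Optional explicit availability probability in
#'   `[0, 1]`, overriding the default mapping from `beta`.
#' @return An object of class `intervention_spec`.
#' @examples
#' intervention_spec(beta = 0.002)
#' @export
intervention_spec <- function(beta = 0, coop_threshold = 0.75,
                              availability = NULL) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0) {
    stop("`beta` must be a single nonnegative number", call. = FALSE)
  }
  check_prob(coop_threshold, "coop_threshold")
  q <- if (is.null(availability)) {
    intervention_availability(beta)
  } else {
    check_prob(availability, "availability")
  }
  structure(list(beta = beta, coop_threshold = coop_threshold,
                 availability = q),
            class = "intervention_spec")
}

#' @export
print.intervention_spec <- function(x, ...) {
  cat(sprintf("<intervention_spec> beta = %g, availability q = %g, threshold = %g\n",
              x$beta, x$availability, x$coop_threshold))
  invisible(x)
}

#' Effective awareness under a perceptual intervention
#'
#' The intervention is an independent information channel: at each new
#' partner choice (after the first interaction), the focal sees the flags
#' with probability `q(beta)` and otherwise falls back on its own awareness,
#' so the probability of identifying a cooperator becomes
#' `1 - (1 - omega)(1 - q(beta))`. With no intervention (or `q = 0`) this is
#' `omega`; with `q = 1` it is 1. The boost applies only from the second
#' partner choice onward (flags cannot exist before the first interaction).
#'
#' @param omega Base awareness in `[0, 1]`.
#' @param intervention An [intervention_spec()] or `NULL`.
#' @return The effective awareness probability.
#' @examples
#' effective_awareness(0.3, intervention_spec(beta = 0))     # 1
#' effective_awareness(0.3, NULL)                            # 0.3
#' @export
effective_awareness <- function(omega, intervention = NULL) {
  check_prob(omega, "omega")
  if (is.null(intervention)) return(omega)
  stopifnot(inherits(intervention, "intervention_spec"))
  1 - (1 - omega) * (1 - intervention$availability)
}
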