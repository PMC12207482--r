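# The association matrix P(i) in vector form: a probability distribution over
# the four partner types, always kept in the canonical order
#   (purple, coop), (purple, defect), (teal, coop), (teal, defect).
# The canonical ordering is used everywhere (the cooperator-only vectors C and
# g are permuted into it) so that convex combinations of like-indexed vectors
# are well defined.

dist_names <- c("p_pc", "p_pd", "p_tc", "p_td")

# type levels matching the canonical order, used for episode records
type_levels <- c("purple_cooperator", "purple_defector",
                 "teal_cooperator", "teal_defector")

new_partner_dist <- function(x) {
  structure(stats::setNames(as.numeric(x), dist_names), class = "partner_dist")
}

#' Partner-type distribution
#'
#' A length-4 probability vector over the partner types in the canonical
#' order (purple cooperator, purple defector, teal cooperator, teal
#' defector). Entries must be nonnegative and sum to 1 within `1e-12`;
#' entries within tolerance of 0 or 1 are clipped to the bound, anything
#' further out raises an error (float noise is forgiven, logic bugs are not).
#'
#' @param p_pc,p_pd,p_tc,p_td Probabilities of the four partner types.
#' @return An object of class `partner_dist` (a named numeric vector).
#' @examples
#' partner_dist(0.25, 0.25, 0.25, 0.25)
#' @export
partner_dist <- function(p_pc, p_pd, p_tc, p_td) {
  as_partner_dist(c(p_pc, p_pd, p_tc, p_td))
}

#' Coerce a length-4 numeric vector to a partner-type distribution
#'
#' @param x A numeric vector of length 4 in canonical type order.
#' @param tol Tolerance for clipping and for the unit-sum check.
#' @return A `partner_dist`.
#' @export
as_partner_dist <- function(x, tol = 1e-12) {
  if (inherits(x, "partner_dist")) return(x)
  x <- as.numeric(x)
  if (length(x) != 4L || anyNA(x)) {
    stop("a partner-type distribution needs 4 non-missing entries", call. = FALSE)
  }
  if (any(x < -tol) || any(x > 1 + tol)) {
    stop("partner-type probabilities must lie in [0, 1]", call. = FALSE)
  }
  x <- pmin(pmax(x, 0), 1)
  if (abs(sum(x) - 1) > tol) {
    stop(sprintf("partner-type probabilities must sum to 1 (got %.15g)", sum(x)),
         call. = FALSE)
  }
  new_partner_dist(x)
}

#' @export
print.partner_dist <- function(x, ...) {
  cat("<partner_dist> (purple/teal x cooperator/defector)\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Probability of pairing with a cooperator
#'
#' `gamma(i) = P_pc(i) + P_tc(i)`, the total cooperator mass of an
#' association distribution.
#'
#' @param P A [partner_dist()].
#' @return A probability.
#' @export
gamma_of <- function(P) {
  P <- as_partner_dist(P)
  unname(P[["p_pc"]] + P[["p_tc"]])
}
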