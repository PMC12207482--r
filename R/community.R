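#' Generate a community roster with a given color-strategy correlation
#'
#' Builds a roster of unconditional agents with exactly half of each color.
#' With `training_bias = c`, the within-color cooperator fractions are
#' `rho = (1 + c)/2` for purple and `tau = (1 - c)/2` for teal (rounded to
#' counts, exact for sizes divisible by 4 and within 1 otherwise), so that
#' half of all agents cooperate, `c = 0` gives color-strategy independence
#' and `c = 1` perfect correlation. Alternatively, explicit `rho`/`tau`
#' cooperator proportions per color may be supplied, in which case the
#' strategy marginal follows them.
#'
#' @param size Positive even number of agents.
#' @param training_bias Color-strategy correlation in `[0, 1]` (default 0,
#'   the unbiased evaluation community).
#' @param rho,tau Optional explicit within-color cooperator proportions
#'   (both must be supplied together; overrides `training_bias`).
#' @return A tibble with columns `id`, `color` (`"purple"`/`"teal"`),
#'   `strategy` (`"cooperator"`/`"defector"`).
#' @examples
#' make_community(8, training_bias = 0.5)
#' @export
make_community <- function(size = 20, training_bias = 0, rho = NULL,
                           tau = NULL) {
  size <- check_count(size, "size", min = 2L)
  if (size %% 2L != 0L) stop("`size` must be even", call. = FALSE)
  n_col <- size %/% 2L
  if (is.null(rho) != is.null(tau)) {
    stop("supply both `rho` and `tau`, or neither", call. = FALSE)
  }
  if (is.null(rho)) {
    pop <- population_from_bias(training_bias)
    n_pc <- as.integer(round(pop$rho * n_col))
    n_tc <- n_col - n_pc # exact half/half strategy marginal
  } else {
    pop <- population_params(rho, tau)
    n_pc <- as.integer(round(pop$rho * n_col))
    n_tc <- as.integer(round(pop$tau * n_col))
  }
  if (n_pc < 0L || n_pc > n_col || n_tc < 0L || n_tc > n_col) {
    stop(sprintf("infeasible cooperator counts for size %d", size),
         call. = FALSE)
  }
  tibble::tibble(
    id = sprintf("a%03d", seq_len(size)),
    color = rep(c("purple", "teal"), each = n_col),
    strategy = c(rep(c("cooperator", "defector"), c(n_pc, n_col - n_pc)),
                 rep(c("cooperator", "defector"), c(n_tc, n_col - n_tc)))
  )
}

#' Realised population parameters of a roster
#'
#' @param community A roster tibble from [make_community()].
#' @return A [population_params()] with the roster's realised within-color
#'   cooperator proportions.
#' @export
community_population <- function(community) {
  stopifnot(all(c("id", "color", "strategy") %in% names(community)))
  frac <- function(col) {
    sub <- community$strategy[community$color == col]
    if (length(sub) == 0L) 0 else mean(sub == "cooperator")
  }
  population_params(rho = frac("purple"), tau = frac("teal"))
}
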