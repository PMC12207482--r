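# Shared fixtures and independent oracles for the test suite.

# Brute-force discrimination index straight off the 2x2 association matrix
# (rows = colors, columns = strategies), independent of the package's
# vectorised formula.
d_brute <- function(p) {
  m <- matrix(p, nrow = 2, byrow = TRUE) # rows: purple, teal; cols: coop, defect
  col_diffs <- sum(abs(m[, 1] - m[, 2]))
  row_diffs <- sum(abs(m[1, ] - m[2, ]))
  col_diffs - row_diffs
}

# Uniform random points on the 4-simplex.
random_simplex <- function(n) {
  x <- matrix(stats::rexp(4 * n), ncol = 4)
  sweep(x, 1, rowSums(x), "/")
}

# Random valid parameter tuples for property tests.
random_params <- function(n) {
  tibble::tibble(
    omega = stats::runif(n), s = stats::runif(n), b = stats::runif(n),
    rho = stats::runif(n), tau = stats::runif(n)
  )
}

# The worked parameterisation used in the hand-derived anchor values.
anchor_focal <- function() focal_params(omega = 0.5, s = 0.5, b = 0.5)
anchor_pop <- function() population_params(rho = 0.75, tau = 0.25)

TEST_SEED <- 20240616L
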