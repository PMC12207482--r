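# internal helpers: argument checks and seed management

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(as.numeric(x))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# Deterministic per-episode child seeds from a root seed, so that growing the
# episode count never perturbs earlier episodes. All arithmetic stays exact in
# doubles (< 2^49) and the result fits a 32-bit integer.
child_seeds <- function(seed, n) {
  i <- seq_len(n)
  as.integer(((as.numeric(seed) %% 2147483629) * 48271 + i * 69621) %%
               2147483629) + 1L
}

# Scoped seeding: functions accept seed = NULL (use the current RNG stream)
# or an integer (deterministic run, caller's RNG state untouched).
local_seed_if <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) {
    withr::local_seed(as.integer(seed), .local_envir = envir)
  }
  invisible(NULL)
}
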