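# Internal helpers: classed conditions and seeded evaluation.
#
# Three error classes partition failure modes across the pipeline:
#   phyto_config_error     -- invalid parameters / configuration
#   phyto_data_error       -- malformed or structurally inconsistent data
#   phyto_degenerate_error -- analyses that are empty or single-class

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("phyto_config_error", "error", "condition")))
}

stop_data <- function(msg) {
  stop(errorCondition(msg, class = c("phyto_data_error", "error", "condition")))
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("phyto_degenerate_error", "error", "condition")))
}

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All stochastic operations in the package route
# through this so that a (config, seed) pair is a pure function of its inputs.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_config("`seed` must be a single non-missing integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Stationary Ornstein-Uhlenbeck noise: correlation time `tau` (s), marginal
# standard deviation `sd`, sampled at step `dt` (s). Consumes n + 1 draws.
ou_noise <- function(n, dt, tau, sd) {
  if (n == 0L || sd <= 0) return(numeric(n))
  rho <- exp(-dt / tau)
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(innov, rho, method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

# First-order leaky low-pass with time constant `tau` (s): one Euler step per
# sample, y <- y + (dt/tau) * (x - y), initialised at x[1].
leaky_lowpass <- function(x, dt, tau) {
  k <- dt / tau
  if (k >= 1) return(x)
  as.numeric(stats::filter(k * x, 1 - k, method = "recursive", init = x[1]))
}

# Smallest odd sample count covering `minutes` at sampling period `period_s`.
odd_window_samples <- function(minutes, period_s) {
  k <- max(1L, as.integer(round(minutes * 60 / period_s)))
  if (k %% 2L == 0L) k <- k + 1L
  k
}

is_binary <- function(x) {
  is.numeric(x) || is.logical(x)
}
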