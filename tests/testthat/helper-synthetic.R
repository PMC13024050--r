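# Shared synthetic fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Default-condition simulation: chamber + plant + labels at a given seed.
default_sim <- function(seed = 17, hours = 72) {
  cached(sprintf("sim_%d_%d", seed, hours), function() {
    env <- simulate_environment(chamber_config(duration_hours = hours, seed = seed))
    plant <- simulate_plant(env, coupling_config(seed = seed + 1))
    labels <- affect_labels(env)
    list(env = env, plant = plant, labels = labels)
  })
}

# Window tables for the two decoding tasks at a given seed.
default_windows <- function(seed = 17, hours = 72) {
  cached(sprintf("win_%d_%d", seed, hours), function() {
    sim <- default_sim(seed, hours)
    list(short = make_windows(sim$plant, sim$labels, window_spec(1, 1)),
         long = make_windows(sim$plant, sim$labels, window_spec(20, 15)))
  })
}

# Minimal hand-built label frame on a uniform timebase (period in seconds).
toy_labels <- function(v, a, valid = rep(TRUE, length(v)), period = 60,
                       V_smooth = 2 * v - 1, A_smooth = 2 * a - 1) {
  n <- length(v)
  structure(
    data.frame(timestamp = (seq_len(n) - 1) * period,
               L_res = numeric(n), V = V_smooth, A = A_smooth,
               V_smooth = V_smooth, A_smooth = A_smooth,
               v = as.integer(v), a = as.integer(a),
               q = 2L * as.integer(v) + as.integer(a), valid = valid),
    period = period, class = c("affect_labels", "data.frame")
  )
}

# Matching plant trace with given channel values (defaults: standard normal).
toy_plant <- function(n, period = 60, bioelectric = NULL, eco2 = NULL,
                      tvoc = NULL, seed = 1) {
  set.seed(seed)
  structure(
    data.frame(timestamp = (seq_len(n) - 1) * period,
               bioelectric = bioelectric %||% rnorm(n),
               eco2 = eco2 %||% rnorm(n, 400, 10),
               tvoc = tvoc %||% rnorm(n, 120, 5)),
    period = period, class = c("plant_trace", "data.frame")
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Hand-built window table: features either informative about the labels
# (feature = sign-coded label plus small noise) or pure noise.
toy_window_table <- function(n = 120, informative = TRUE, seed = 1,
                             stride_seconds = 60) {
  set.seed(seed)
  v <- rep(rep(0:1, each = 10), length.out = n)
  a <- rep(rep(c(1, 0), each = 15), length.out = n)
  mk <- function(y, scale) {
    if (informative) (2 * y - 1) * scale + rnorm(n, 0, 0.1 * scale) else rnorm(n, 0, scale)
  }
  wt <- data.frame(
    window_start = (seq_len(n) - 1) * stride_seconds,
    window_end = seq_len(n) * stride_seconds,
    n_samples = 30L, n_valid = 30L,
    bioelectric_mean = mk(a, 2), bioelectric_sd = abs(rnorm(n, 1, 0.1)),
    eco2_mean = mk(v, 40) + 400, eco2_sd = abs(rnorm(n, 10, 1)),
    tvoc_mean = mk(v, 20) + 120, tvoc_sd = abs(rnorm(n, 5, 0.5)),
    V_mean = 2 * v - 1, A_mean = 2 * a - 1,
    label_v = v, label_a = a, label_q = 2L * v + a
  )
  structure(wt,
            feature_cols = c("bioelectric_mean", "bioelectric_sd", "eco2_mean",
                             "eco2_sd", "tvoc_mean", "tvoc_sd"),
            stride_seconds = stride_seconds, period = 2,
            spec = window_spec(1, 1),
            class = c("window_table", "data.frame"))
}
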