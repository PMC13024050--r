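#' Chamber simulation settings
#'
#' Parameters of the synthetic growth chamber. The chamber follows the
#' recording protocol of the physical apparatus the package emulates: ambient
#' temperature near 25 degC, heater pulses of random onset lasting 15-45 min,
#' extractor fans triggered at a critical 36 degC and holding the chamber
#' above 35 degC while the heat episode lasts, a fresh-air flush every 24 h,
#' a diurnal light cycle, and humidity anti-coupled to temperature.
#' Environmental channels are sampled at \code{env_rate} Hz (default 0.5 Hz).
#'
#' @param duration_hours total simulated time in hours.
#' @param env_rate sampling rate of all environmental channels, samples/s.
#' @param ambient_temp baseline chamber temperature, degC.
#' @param fan_trigger_temp temperature at which fans engage, degC.
#' @param fan_floor_temp temperature the fans hold during a heat episode, degC.
#' @param heater_min,heater_max heater episode duration bounds, minutes.
#' @param heater_rate expected heater onsets per day (homogeneous Poisson
#'   process, refractory while an episode is active).
#' @param heater_target asymptotic temperature the heater drives toward, degC.
#' @param tau_temp thermal relaxation time constant, seconds.
#' @param tau_fan fan-driven cooling time constant, seconds.
#' @param flush_period interval between fresh-air fan flushes, hours.
#' @param flush_duration length of each flush, minutes.
#' @param diurnal_period light cycle period, hours.
#' @param light_amplitude peak of the diurnal light waveform, sensor units.
#' @param light_temp_gain passive heating of the chamber by light,
#'   degC per light unit (set 0 for a light-decoupled thermal model).
#' @param humidity_base baseline relative humidity, %RH.
#' @param humidity_temp_gain humidity change per degC above ambient
#'   (negative: warm air in the closed chamber reads drier), %RH/degC.
#' @param temp_noise_sd,humidity_noise_sd,light_noise_sd,ir_noise_sd marginal
#'   standard deviations of the smooth (Ornstein-Uhlenbeck) sensor noise on
#'   each channel, in channel units.
#' @param seed integer seed; the trace is a pure function of (config, seed).
#'
#' @return An object of class \code{chamber_config}.
#' @seealso [simulate_environment()]
#' @export
chamber_config <- function(duration_hours = 72,
                           env_rate = 0.5,
                           ambient_temp = 25,
                           fan_trigger_temp = 36,
                           fan_floor_temp = 35,
                           heater_min = 15,
                           heater_max = 45,
                           heater_rate = 24,
                           heater_target = 48,
                           tau_temp = 600,
                           tau_fan = 120,
                           flush_period = 24,
                           flush_duration = 10,
                           diurnal_period = 24,
                           light_amplitude = 250,
                           light_temp_gain = 0.01,
                           humidity_base = 55,
                           humidity_temp_gain = -1.5,
                           temp_noise_sd = 0.15,
                           humidity_noise_sd = 4,
                           light_noise_sd = 15,
                           ir_noise_sd = 0.3,
                           seed = 1L) {
  if (duration_hours <= 0) stop_config("`duration_hours` must be positive")
  if (env_rate <= 0) stop_config("`env_rate` must be positive")
  if (heater_min > heater_max) stop_config("`heater_min` must not exceed `heater_max`")
  if (heater_min <= 0) stop_config("heater episode durations must be positive")
  if (fan_floor_temp >= fan_trigger_temp) {
    stop_config("`fan_floor_temp` must be below `fan_trigger_temp`")
  }
  if (heater_rate < 0) stop_config("`heater_rate` must be non-negative")
  if (flush_period <= 0 || diurnal_period <= 0) {
    stop_config("`flush_period` and `diurnal_period` must be positive")
  }
  structure(as.list(environment()), class = "chamber_config")
}

#' Simulate a chamber environment trace
#'
#' Generates the four environmental channels (temperature, relative humidity,
#' light, infrared) plus the binary heater and fan event channels on a uniform
#' timebase. Temperature follows a first-order relaxation toward ambient,
#' driven upward while the heater is on; whenever it reaches
#' \code{fan_trigger_temp} the fans engage, cool the chamber, and hold it at or
#' above \code{fan_floor_temp} until the heat episode ends. Heater onsets form
#' a memoryless (Poisson) process at \code{heater_rate} per day, refractory
#' while an episode is active, with each episode duration drawn uniformly in
#' \code{[heater_min, heater_max]} minutes. Fans additionally run for a fixed
#' flush window every \code{flush_period} hours. Light is a non-negative
#' half-rectified diurnal sinusoid plus a heater-correlated component and
#' smooth noise; humidity is anti-coupled to temperature and clipped to
#' \code{[0, 100]} %RH.
#'
#' @param config a [chamber_config()].
#' @return A data frame of class \code{environment_trace} with columns
#'   \code{timestamp} (seconds from trace start), \code{temperature},
#'   \code{humidity}, \code{light}, \code{infrared}, \code{heater},
#'   \code{fan}; sampling period stored in \code{attr(, "period")}.
#' @examples
#' env <- simulate_environment(chamber_config(duration_hours = 6, seed = 7))
#' range(env$humidity)
#' @export
simulate_environment <- function(config) {
  if (!inherits(config, "chamber_config")) {
    stop_config("`config` must be a chamber_config object")
  }
  dt <- 1 / config$env_rate
  n <- as.integer(round(config$duration_hours * 3600 * config$env_rate))
  if (n < 2L) stop_config("duration too short for the configured sampling rate")
  tt <- (seq_len(n) - 1) * dt

  with_seed(config$seed, {
    ## --- heater schedule: Poisson onsets, uniform episode durations -------
    heater <- logical(n)
    p_on <- config$heater_rate * dt / 86400
    onset_draw <- stats::runif(n)
    i <- 1L
    while (i <= n) {
      if (p_on > 0 && onset_draw[i] < p_on) {
        dur_min <- stats::runif(1, config$heater_min, config$heater_max)
        len <- max(1L, as.integer(round(dur_min * 60 / dt)))
        heater[i:min(n, i + len - 1L)] <- TRUE
        # one-sample refractory gap so consecutive episodes never fuse
        i <- i + len + 1L
      } else {
        i <- i + 1L
      }
    }

    ## --- scheduled fresh-air flushes ---------------------------------------
    flush <- logical(n)
    flush_starts <- seq(config$flush_period * 3600, by = config$flush_period * 3600,
                        length.out = max(0, floor(config$duration_hours / config$flush_period)))
    flush_len <- max(1L, as.integer(round(config$flush_duration * 60 / dt)))
    for (s in flush_starts) {
      i0 <- as.integer(floor(s / dt)) + 1L
      if (i0 <= n) flush[i0:min(n, i0 + flush_len - 1L)] <- TRUE
    }

    ## --- light: half-rectified diurnal + heater-correlated + smooth noise --
    hours <- tt / 3600
    diurnal <- pmax(0, sin(2 * pi * (hours - 6) / config$diurnal_period))
    heater_lp <- leaky_lowpass(as.numeric(heater), dt, 300)
    light_det <- config$light_amplitude * diurnal + 5 * heater_lp
    light <- pmax(0, light_det + ou_noise(n, dt, 1200, config$light_noise_sd))

    ## --- temperature: Euler relaxation with thermostat hysteresis ----------
    # Stochastic forcing enters the dynamics (not the measurement) so the
    # fan-trigger invariant holds exactly on recorded samples.
    innov <- stats::rnorm(n, 0, config$temp_noise_sd * sqrt(2 * dt / config$tau_temp))
    temp <- numeric(n)
    fan <- logical(n)
    Tcur <- config$ambient_temp
    fan_on <- FALSE
    for (k in seq_len(n)) {
      amb <- config$ambient_temp + config$light_temp_gain * light_det[k]
      if (flush[k]) {
        Tcur <- Tcur + dt * (amb - Tcur) / config$tau_fan + innov[k]
      } else if (fan_on) {
        Tcur <- Tcur + dt * (config$fan_floor_temp - Tcur) / config$tau_fan + innov[k]
      } else if (heater[k]) {
        Tcur <- Tcur + dt * (config$heater_target - Tcur) / config$tau_temp + innov[k]
      } else {
        Tcur <- Tcur + dt * (amb - Tcur) / config$tau_temp + innov[k]
      }
      # thermostat: engage on the very sample the trigger is reached, so no
      # recorded sample ever exceeds the trigger with the fans off
      if (Tcur >= config$fan_trigger_temp) fan_on <- TRUE
      if (heater[k] && fan_on) Tcur <- max(Tcur, config$fan_floor_temp)
      if (fan_on && Tcur <= config$fan_floor_temp + 0.05) fan_on <- FALSE
      temp[k] <- Tcur
      fan[k] <- fan_on || flush[k]
    }

    ## --- humidity: anti-coupled to temperature, smooth noise, clipped ------
    humidity <- config$humidity_base +
      config$humidity_temp_gain * (temp - config$ambient_temp) +
      ou_noise(n, dt, 7200, config$humidity_noise_sd)
    humidity <- pmin(100, pmax(0, humidity))

    ## --- infrared: warm bodies and daylight both radiate -------------------
    infrared <- pmax(0, 1.5 + 0.008 * light + 0.25 * (temp - config$ambient_temp) +
                       ou_noise(n, dt, 1800, config$ir_noise_sd))

    structure(
      data.frame(timestamp = tt, temperature = temp, humidity = humidity,
                 light = light, infrared = infrared,
                 heater = as.integer(heater), fan = as.integer(fan)),
      period = dt, config = config,
      class = c("environment_trace", "data.frame")
    )
  })
}

#' Plant-signal coupling settings
#'
#' Parameters of the statistical plant model. The model encodes the
#' timescale-separation hypothesis under test: arousal-related internal
#' dynamics are fast (the bioelectric channel tracks the level of the arousal
#' drive through a leaky filter with a short time constant \code{tau_fast},
#' like a sustained depolarisation following stress onset within a minute or
#' so), while valence-related dynamics are slow (the gas channels
#' leak-integrate the valence drive with the much longer time constant
#' \code{tau_slow}). Drives are computed internally from the true
#' environmental variables with the same residual-light construction used for
#' labelling, so the labelling stage downstream remains an honest estimation
#' step.
#'
#' @param fast_gain dimensionless coupling of the arousal drive into the
#'   bioelectric channel; 0 disconnects the channel from the environment.
#' @param slow_gain dimensionless coupling of the valence drive into the gas
#'   channels (eCO2, TVOC).
#' @param tau_fast response time constant of the bioelectric coupling,
#'   seconds (must be shorter than \code{tau_slow}).
#' @param tau_slow leaky-integration time constant of the gas coupling, seconds.
#' @param noise_sd_bio,noise_sd_gas white-noise standard deviations in drive
#'   (z-score) units, scaled into channel units with the couplings.
#' @param drift_sd random-walk drift accumulated by the gas channels,
#'   drive units per sqrt(hour); models slow metal-oxide sensor baseline drift.
#' @param seed integer seed.
#' @return An object of class \code{coupling_config}.
#' @seealso [simulate_plant()]
#' @export
coupling_config <- function(fast_gain = 3,
                            slow_gain = 3,
                            tau_fast = 60,
                            tau_slow = 1800,
                            noise_sd_bio = 0.3,
                            noise_sd_gas = 0.3,
                            drift_sd = 0.1,
                            seed = 1L) {
  if (tau_fast >= tau_slow) stop_config("`tau_fast` must be shorter than `tau_slow`")
  if (tau_fast <= 0) stop_config("time constants must be positive")
  if (noise_sd_bio < 0 || noise_sd_gas < 0 || drift_sd < 0) {
    stop_config("noise standard deviations must be non-negative")
  }
  structure(as.list(environment()), class = "coupling_config")
}

#' Simulate internal plant signals coupled to a chamber environment
#'
#' Generates the three internal channels the decoders are allowed to see:
#' a differential bioelectric potential (mV scale) and two gas-emission
#' proxies (eCO2 in ppm, TVOC in ppb). The bioelectric channel carries
#' \code{fast_gain} times a fast leaky filter (response time
#' \code{tau_fast}) of the arousal drive plus white noise, so it tracks the
#' arousal level with a lag of about a minute; the gas channels carry
#' \code{slow_gain} times a leaky integration (time constant
#' \code{tau_slow}) of the valence drive plus random-walk sensor drift and
#' noise. Both drives are computed from the true environmental variables via
#' the residual-light valence/arousal construction (see [affect_labels()]).
#'
#' @param env an [simulate_environment()] trace.
#' @param coupling a [coupling_config()].
#' @return A data frame of class \code{plant_trace} with columns
#'   \code{timestamp}, \code{bioelectric}, \code{eco2}, \code{tvoc}, on the
#'   same timebase as \code{env}.
#' @export
simulate_plant <- function(env, coupling) {
  if (!inherits(env, "environment_trace")) {
    stop_data("`env` must be an environment_trace")
  }
  if (!inherits(coupling, "coupling_config")) {
    stop_config("`coupling` must be a coupling_config object")
  }
  n <- nrow(env)
  cols <- c("temperature", "humidity", "light")
  if (any(!cols %in% names(env)) ||
      length(unique(vapply(env[cols], length, 0L))) != 1L) {
    stop_data("environment trace channels are missing or of unequal length")
  }
  dt <- attr(env, "period")
  if (is.null(dt)) dt <- stats::median(diff(env$timestamp))

  # True (unobserved) affect drives from the environment.
  zT <- zscore(env$temperature)
  zH <- zscore(env$humidity)
  zL <- zscore(env$light)
  res <- fit_residual_light(zL, zT, zH)
  va <- valence_arousal(res$L_res, zT, zH)

  # channel scale constants: drive z-units -> physical sensor units
  bio_scale <- 5     # mV per drive unit
  eco2_base <- 400; eco2_scale <- 60   # ppm
  tvoc_base <- 120; tvoc_scale <- 40   # ppb

  with_seed(coupling$seed, {
    a_fast <- leaky_lowpass(va$A, dt, coupling$tau_fast)
    v_slow <- leaky_lowpass(va$V, dt, coupling$tau_slow)

    step_sd <- coupling$drift_sd * sqrt(dt / 3600)
    drift_e <- if (step_sd > 0) cumsum(stats::rnorm(n, 0, step_sd)) else numeric(n)
    drift_t <- if (step_sd > 0) cumsum(stats::rnorm(n, 0, step_sd)) else numeric(n)

    bio <- bio_scale * (coupling$fast_gain * a_fast +
                          stats::rnorm(n, 0, coupling$noise_sd_bio))
    eco2 <- eco2_base + eco2_scale * (coupling$slow_gain * v_slow + drift_e +
                                        stats::rnorm(n, 0, coupling$noise_sd_gas))
    tvoc <- tvoc_base + tvoc_scale * (coupling$slow_gain * v_slow + drift_t +
                                        stats::rnorm(n, 0, coupling$noise_sd_gas))

    structure(
      data.frame(timestamp = env$timestamp, bioelectric = bio,
                 eco2 = eco2, tvoc = tvoc),
      period = dt, coupling = coupling,
      class = c("plant_trace", "data.frame")
    )
  })
}
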