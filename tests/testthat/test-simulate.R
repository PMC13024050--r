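test_that("trace generation is a pure function of config and seed", {
  cfg <- chamber_config(duration_hours = 6, seed = 42)
  e1 <- simulate_environment(cfg)
  e2 <- simulate_environment(cfg)
  expect_identical(e1, e2)
  e3 <- simulate_environment(chamber_config(duration_hours = 6, seed = 43))
  expect_false(identical(e1$temperature, e3$temperature))

  cp <- coupling_config(seed = 7)
  expect_identical(simulate_plant(e1, cp), simulate_plant(e1, cp))
})

test_that("every heater episode lasts between 15 and 45 minutes", {
  # coarse sampling + high onset rate to pack many episodes into one trace
  cfg <- chamber_config(duration_hours = 240, env_rate = 0.1,
                        heater_rate = 100, seed = 3)
  env <- simulate_environment(cfg)
  r <- rle(env$heater)
  on_runs <- r$lengths[r$values == 1]
  # an episode truncated by the end of the trace is not a full episode
  if (env$heater[nrow(env)] == 1) on_runs <- on_runs[-length(on_runs)]
  expect_gt(length(on_runs), 200)
  dur_min <- on_runs * (1 / cfg$env_rate) / 60
  expect_true(all(dur_min >= 15 - 1e-9))
  expect_true(all(dur_min <= 45 + 1e-9))
})

test_that("without forcing, temperature relaxes to ambient", {
  cfg <- chamber_config(duration_hours = 12, heater_rate = 0,
                        light_temp_gain = 0, temp_noise_sd = 0, seed = 5)
  env <- simulate_environment(cfg)
  late <- env$temperature[env$timestamp > 6 * 3600]
  expect_lt(max(abs(late - 25)), 0.01)
  expect_equal(sum(env$heater), 0)
})

test_that("the fan engages at the trigger and holds the floor", {
  env <- default_sim(17, 96)$env
  expect_equal(mean(env$temperature > 36 & env$fan == 0), 0)
  # thermostat hold: at or above the floor while the episode persists
  # (scheduled fresh-air flushes cool freely and are excluded)
  flush <- rep(FALSE, nrow(env))
  for (s in seq(24 * 3600, 96 * 3600, by = 24 * 3600)) {
    flush[env$timestamp >= s & env$timestamp < s + 600] <- TRUE
  }
  hold <- env$heater == 1 & env$fan == 1 & !flush
  expect_gt(sum(hold), 0)
  expect_true(all(env$temperature[hold] >= 35))
})

test_that("physical bounds hold on generated traces", {
  env <- default_sim(17)$env
  expect_true(all(env$humidity >= 0 & env$humidity <= 100))
  expect_true(all(env$light >= 0))
  expect_true(all(env$heater %in% 0:1))
  expect_true(all(env$fan %in% 0:1))
  expect_true(all(diff(env$timestamp) == 2))
})

test_that("humidity is anti-coupled to temperature", {
  env <- default_sim(17)$env
  expect_lt(cor(env$temperature, env$humidity), -0.5)
})

test_that("the induced affect coordinates occupy all four quadrants over 72 h", {
  lab <- default_sim(17)$labels
  occ <- table(factor(lab$q[lab$valid], levels = 0:3))
  expect_true(all(occ > 0))
})

test_that("zero coupling leaves plant channels uncorrelated with the drives", {
  env <- simulate_environment(chamber_config(duration_hours = 24, seed = 9))
  plant <- simulate_plant(env, coupling_config(fast_gain = 0, slow_gain = 0,
                                               drift_sd = 0, seed = 10))
  lab <- affect_labels(env)
  for (ch in c("bioelectric", "eco2", "tvoc")) {
    expect_lt(abs(cor(plant[[ch]], lab$V)), 0.05)
    expect_lt(abs(cor(plant[[ch]], lab$A)), 0.05)
  }
})

test_that("strong slow coupling with low noise makes gas track integrated valence", {
  env <- simulate_environment(chamber_config(duration_hours = 24, seed = 9))
  cp <- coupling_config(slow_gain = 10, noise_sd_gas = 0.05, drift_sd = 0, seed = 10)
  plant <- simulate_plant(env, cp)
  # independent reconstruction of the leaky-integrated valence drive
  zT <- zscore(env$temperature); zH <- zscore(env$humidity); zL <- zscore(env$light)
  V <- valence_arousal(fit_residual_light(zL, zT, zH)$L_res, zT, zH)$V
  k <- 2 / cp$tau_slow
  v_slow <- as.numeric(stats::filter(k * V, 1 - k, "recursive", init = V[1]))
  expect_gt(cor(v_slow, plant$eco2), 0.9)
})

test_that("decoding accuracy is non-decreasing in the coupling gains", {
  gains <- c(0, 1.5, 3)
  seeds <- 101:105
  ba <- array(NA_real_, c(2, length(gains), length(seeds)))
  for (si in seq_along(seeds)) {
    env <- simulate_environment(chamber_config(duration_hours = 36, seed = seeds[si]))
    lab <- affect_labels(env)
    for (gi in seq_along(gains)) {
      plant <- simulate_plant(env, coupling_config(fast_gain = gains[gi],
                                                   slow_gain = gains[gi],
                                                   seed = seeds[si] + 1))
      ws <- make_windows(plant, lab, window_spec(1, 1))
      wl <- make_windows(plant, lab, window_spec(20, 15))
      ba[1, gi, si] <- evaluate_pipeline(ws, "arousal")$mean["balanced_accuracy"]
      ba[2, gi, si] <- evaluate_pipeline(wl, "valence")$mean["balanced_accuracy"]
    }
  }
  m <- apply(ba, c(1, 2), mean)
  expect_true(all(diff(m[1, ]) > -0.01))  # arousal vs fast_gain
  expect_true(all(diff(m[2, ]) > -0.01))  # valence vs slow_gain
  # and coupling beats no coupling outright
  expect_gt(m[1, 3], m[1, 1] + 0.1)
  expect_gt(m[2, 3], m[2, 1] + 0.1)
})

test_that("invalid chamber configurations are refused", {
  expect_error(chamber_config(duration_hours = -1), class = "phyto_config_error")
  expect_error(chamber_config(env_rate = 0), class = "phyto_config_error")
  expect_error(chamber_config(heater_min = 50, heater_max = 45),
               class = "phyto_config_error")
  expect_error(chamber_config(fan_floor_temp = 37), class = "phyto_config_error")
  expect_error(coupling_config(tau_fast = 2000, tau_slow = 1800),
               class = "phyto_config_error")
  expect_error(coupling_config(noise_sd_bio = -1), class = "phyto_config_error")
})
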