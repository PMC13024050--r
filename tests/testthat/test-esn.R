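test_that("the recurrent matrix is rescaled to the requested spectral radius", {
  for (seed in 1:3) {
    res <- init_reservoir(reservoir_config(seed = seed), n_inputs = 4)
    sr <- max(Mod(eigen(res$W, only.values = TRUE)$values))
    expect_equal(sr, 0.9, tolerance = 1e-6)
  }
})

test_that("reservoir initialisation is deterministic and respects scaling", {
  cfg <- reservoir_config(seed = 11)
  r1 <- init_reservoir(cfg, 3)
  r2 <- init_reservoir(cfg, 3)
  expect_identical(r1$W, r2$W)
  expect_identical(r1$W_in, r2$W_in)
  r0 <- init_reservoir(reservoir_config(input_scaling = 0, seed = 11), 3)
  expect_true(all(r0$W_in == 0))
})

test_that("the state update has the correct fixed point and memoryless limit", {
  res <- init_reservoir(reservoir_config(n_units = 20, seed = 2), 2)
  U <- matrix(0, 10, 2)
  expect_true(all(run_reservoir(res, U) == 0))

  # leak = 1 with W = 0 reduces to x(t+1) = tanh(W_in u(t))
  res1 <- init_reservoir(reservoir_config(n_units = 10, leak = 1, seed = 3), 2)
  res1$W[] <- 0
  set.seed(4)
  U <- matrix(rnorm(10), 5, 2)
  X <- run_reservoir(res1, U)
  expect_equal(X, t(tanh(res1$W_in %*% t(U))), tolerance = 1e-12)
})

test_that("a 3-unit reservoir matches a hand-unrolled iteration", {
  W <- matrix(c(0.1, -0.2, 0.05, 0.3, 0, -0.1, 0, 0.2, 0.15), 3, 3)
  W_in <- matrix(c(0.5, -0.3, 0.2), 3, 1)
  res <- structure(list(W = W, W_in = W_in,
                        config = reservoir_config(n_units = 3, leak = 0.2),
                        n_inputs = 1L), class = "reservoir")
  U <- matrix(c(1, -1, 0.5, 0, 2), 5, 1)
  X <- run_reservoir(res, U)
  x <- c(0, 0, 0)
  for (t in 1:5) {
    x <- 0.8 * x + 0.2 * tanh(drop(W_in %*% U[t, ]) + drop(W %*% x))
    expect_equal(X[t, ], x, tolerance = 1e-12)
  }
})

test_that("states stay in [-1, 1] and fade without input", {
  res <- init_reservoir(reservoir_config(n_units = 50, seed = 5), 2)
  set.seed(6)
  U <- matrix(rnorm(400, sd = 10), 200, 2)
  X <- run_reservoir(res, U)
  expect_true(all(X >= -1 & X <= 1))
  # spectral radius < 1, zero input: the state contracts to the origin
  x0 <- runif(50, -1, 1)
  Xz <- run_reservoir(res, matrix(0, 800, 2), x0 = x0)
  expect_lt(max(abs(Xz[800, ])), 1e-3)
  expect_lt(max(abs(Xz[800, ])), max(abs(Xz[1, ])))
})

test_that("the initial state washes out on identical input", {
  res <- init_reservoir(reservoir_config(seed = 7), 3)
  set.seed(8)
  U <- matrix(rnorm(4500), 1500, 3)
  X0 <- run_reservoir(res, U)
  Xr <- run_reservoir(res, U, x0 = runif(300, -1, 1))
  expect_lt(max(abs(X0[1500, ] - Xr[1500, ])), 1e-6)
})

test_that("non-finite input is reported with its step", {
  res <- init_reservoir(reservoir_config(n_units = 10, density = 0.5, seed = 9), 1)
  U <- matrix(c(1, 2, NA, 4), 4, 1)
  expect_error(run_reservoir(res, U), "step 3", class = "phyto_data_error")
})

test_that("the ridge readout matches an independent augmented-QR oracle", {
  set.seed(10)
  X <- matrix(rnorm(80), 10, 8)
  y <- rep(c(0, 1), 5)
  lambda <- 1.7
  m <- fit_readout(X, y, ridge_penalty = lambda)
  # oracle: ridge as augmented least squares solved by QR (bias unpenalised)
  Z <- cbind(X, 1)
  aug <- rbind(Z, cbind(sqrt(lambda) * diag(8), 0))
  w_oracle <- qr.solve(aug, c(2 * y - 1, rep(0, 8)))
  expect_equal(unname(m$W_out), unname(w_oracle), tolerance = 1e-8)
})

test_that("ridge limits behave: heavy penalty shrinks weights to the class mean", {
  set.seed(11)
  X <- matrix(rnorm(300), 50, 6)
  y <- rep(c(0, 1), 25)
  m <- fit_readout(X, y, ridge_penalty = 1e10)
  expect_lt(max(abs(m$W_out[1:6])), 1e-6)
  expect_equal(m$W_out[7], mean(2 * y - 1), tolerance = 1e-4)
})

test_that("an exactly realisable system is interpolated at zero penalty", {
  set.seed(12)
  X <- matrix(rnorm(20), 5, 4)        # [X, 1] is square and full rank
  w_true <- c(1, 0, 0, 0, 0)          # scores realisable as X[, 1]
  s <- drop(cbind(X, 1) %*% w_true)
  y <- as.integer(s > 0)
  stopifnot(length(unique(y)) == 2)
  m <- fit_readout(X, y, ridge_penalty = 0)
  pred <- predict_binary(m, X)
  expect_equal(pred$class, y)
  expect_equal(pred$score, 2 * y - 1, tolerance = 1e-8)
})

test_that("single-class targets and excessive washout are degenerate", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(fit_readout(X, rep(1, 10)), class = "phyto_degenerate_error")
  expect_error(fit_readout(X, rep(c(0, 1), 5), washout = 10),
               class = "phyto_degenerate_error")
  # washout drops leading rows: fitting on rows 3..10 only
  y <- c(1, 1, rep(c(0, 1), 4))
  m <- fit_readout(X, y, washout = 2)
  m2 <- fit_readout(X[3:10, ], y[3:10])
  expect_equal(m$W_out, m2$W_out)
})

test_that("scores map through the sigmoid and threshold consistently", {
  m <- structure(list(W_out = c(0, 0, 0), ridge_penalty = 1, washout = 0L,
                      n_train = 10L), class = "esn_readout")
  X <- matrix(0, 1, 2)
  p <- predict_binary(m, X)       # score exactly 0
  expect_equal(p$prob, 0.5)
  expect_equal(p$class, 0L)       # strict threshold: 0.5 is class 0
  m$W_out <- c(0, 0, 4)
  p4 <- predict_binary(m, X)      # score 4
  expect_equal(p4$prob, 1 / (1 + exp(-4)), tolerance = 1e-12)
  expect_equal(p4$class, 1L)
  set.seed(13)
  mr <- structure(list(W_out = rnorm(3)), class = "esn_readout")
  Xr <- matrix(rnorm(60), 30, 2)
  pr <- predict_binary(mr, Xr)
  expect_equal(pr$class, as.integer(pr$score > 0))
})

test_that("quadrant combination composes binary predictions", {
  expect_equal(combine_quadrant(1, 0), 2L)
  expect_equal(combine_quadrant(0, 1), 1L)
  set.seed(14)
  v_true <- rbinom(200, 1, 0.5); a_true <- rbinom(200, 1, 0.5)
  q_true <- 2 * v_true + a_true
  expect_equal(mean(combine_quadrant(v_true, a_true) == q_true), 1)
  a_noisy <- ifelse(runif(200) < 0.3, 1 - a_true, a_true)
  expect_equal(mean(combine_quadrant(v_true, a_noisy) == q_true),
               mean(a_noisy == a_true))
  expect_error(combine_quadrant(c(0, 1), 1), class = "phyto_data_error")
})

test_that("the reservoir can decode a one-step-delayed binary input", {
  # the leak rate is the reservoir timescale: a white +/-1 stream needs a
  # faster integrator than the slow-biosignal default of 0.2
  cfg <- reservoir_config(leak = 0.5, seed = 15)
  res <- init_reservoir(cfg, 1)
  set.seed(16)
  u <- sample(c(-1, 1), 600, replace = TRUE)
  y <- c(0L, as.integer(u[-600] > 0))   # delayed copy
  X <- run_reservoir(res, matrix(u, ncol = 1))
  m <- fit_readout(X[1:400, ], y[1:400], ridge_penalty = cfg$ridge_penalty,
                   washout = cfg$washout)
  acc <- mean(predict_binary(m, X[401:600, ])$class == y[401:600])
  expect_gt(acc, 0.95)
})

test_that("a serialised model restores to identical weights and predictions", {
  res <- init_reservoir(reservoir_config(n_units = 40, seed = 17), 2)
  set.seed(18)
  U <- matrix(rnorm(200), 100, 2)
  X <- run_reservoir(res, U)
  m <- fit_readout(X, rep(c(0, 1), 50), washout = 10)
  path <- tempfile(fileext = ".json")
  write_esn(res, m, path)
  back <- read_esn(path)
  expect_equal(back$reservoir$W, res$W)
  expect_equal(back$reservoir$W_in, res$W_in)
  expect_equal(back$readout$W_out, m$W_out, tolerance = 1e-12)
  expect_equal(predict_binary(back$readout, X)$class,
               predict_binary(m, X)$class)
})
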