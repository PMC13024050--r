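#' Echo state network settings
#'
#' Defaults follow standard reservoir-computing practice for slow biosignals:
#' 300 leaky-integrator units, spectral radius 0.9, leak rate 0.2, input
#' scaling 0.5, a 50-step washout, and a ridge readout with penalty 1.0. The
#' leak rate and the ridge penalty are distinct parameters. Recurrent weights
#' are drawn i.i.d. Uniform(-1, 1), sparsified to \code{density}, then
#' rescaled to the requested spectral radius; they are never trained.
#'
#' @param n_units reservoir size.
#' @param spectral_radius largest absolute eigenvalue of the recurrent matrix
#'   after rescaling; below 1 promotes fading memory.
#' @param leak leak rate in (0, 1]: convex-combination weight of the state
#'   update \code{x(t+1) = (1 - leak) x(t) + leak tanh(W_in u(t) + W x(t))}.
#' @param input_scaling multiplier applied to the dense input weights.
#' @param washout initial reservoir steps excluded from readout training.
#' @param ridge_penalty L2 penalty of the linear readout (bias unpenalised).
#' @param density fraction of nonzero recurrent weights.
#' @param seed integer seed for weight initialisation.
#' @return An object of class \code{reservoir_config}.
#' @export
reservoir_config <- function(n_units = 300L,
                             spectral_radius = 0.9,
                             leak = 0.2,
                             input_scaling = 0.5,
                             washout = 50L,
                             ridge_penalty = 1.0,
                             density = 0.1,
                             seed = 1L) {
  if (n_units <= 0) stop_config("`n_units` must be positive")
  if (leak <= 0 || leak > 1) stop_config("`leak` must be in (0, 1]")
  if (spectral_radius <= 0) stop_config("`spectral_radius` must be positive")
  if (washout < 0) stop_config("`washout` must be >= 0")
  if (ridge_penalty < 0) stop_config("`ridge_penalty` must be >= 0")
  if (density <= 0 || density > 1) stop_config("`density` must be in (0, 1]")
  structure(list(n_units = as.integer(n_units), spectral_radius = spectral_radius,
                 leak = leak, input_scaling = input_scaling,
                 washout = as.integer(washout), ridge_penalty = ridge_penalty,
                 density = density, seed = seed),
            class = "reservoir_config")
}

#' Initialise a fixed random reservoir
#'
#' Draws the recurrent matrix \code{W} (i.i.d. Uniform(-1, 1), sparsified to
#' the configured density, rescaled so its spectral radius equals
#' \code{spectral_radius} to within 1e-6) and the dense input matrix
#' \code{W_in} (i.i.d. Uniform(-1, 1) times \code{input_scaling}). Identical
#' (config, n_inputs) pairs yield identical matrices.
#'
#' @param config a [reservoir_config()].
#' @param n_inputs number of input channels.
#' @return An object of class \code{reservoir} with elements \code{W},
#'   \code{W_in}, \code{config}, \code{n_inputs}.
#' @export
init_reservoir <- function(config, n_inputs) {
  if (!inherits(config, "reservoir_config")) {
    stop_config("`config` must be a reservoir_config")
  }
  if (n_inputs < 1) stop_config("`n_inputs` must be at least 1")
  n <- config$n_units
  with_seed(config$seed, {
    W <- matrix(stats::runif(n * n, -1, 1), n, n)
    keep <- matrix(stats::runif(n * n) < config$density, n, n)
    W[!keep] <- 0
    sr <- max(Mod(eigen(W, only.values = TRUE)$values))
    if (sr == 0) {
      stop_config(paste("sparsification produced a nilpotent/zero recurrent matrix",
                        "(spectral radius 0); increase `density` or `n_units`,",
                        "or change the seed"))
    }
    W <- W * (config$spectral_radius / sr)
    W_in <- matrix(stats::runif(n * n_inputs, -1, 1), n, n_inputs) * config$input_scaling
    structure(list(W = W, W_in = W_in, config = config,
                   n_inputs = as.integer(n_inputs)),
              class = "reservoir")
  })
}

#' Drive a reservoir with an input sequence
#'
#' Iterates the leaky-integrator update
#' \code{x(t+1) = (1 - leak) x(t) + leak tanh(W_in u(t) + W x(t))}
#' over the rows of \code{U}, starting from \code{x0} (zeros by default).
#' Row t of the returned state matrix is the state after absorbing input t.
#' With \code{x0} inside \code{[-1, 1]} every state stays inside
#' \code{[-1, 1]} elementwise (each update is a convex combination of the
#' previous state and a tanh image).
#'
#' @param res a [init_reservoir()] object.
#' @param U numeric matrix \code{[T x n_inputs]} (a vector is treated as one
#'   input channel).
#' @param x0 optional initial state of length \code{n_units}.
#' @return Numeric matrix \code{[T x n_units]} of reservoir states.
#' @export
run_reservoir <- function(res, U, x0 = NULL) {
  if (!inherits(res, "reservoir")) stop_config("`res` must be a reservoir")
  if (is.vector(U)) U <- matrix(U, ncol = 1L)
  if (ncol(U) != res$n_inputs) {
    stop_data(sprintf("input has %d channels; reservoir expects %d",
                      ncol(U), res$n_inputs))
  }
  bad <- which(!is.finite(U), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_data(sprintf("non-finite input at step %d (channel %d)",
                      bad[1, 1], bad[1, 2]))
  }
  n <- res$config$n_units
  a <- res$config$leak
  if (is.null(x0)) x0 <- numeric(n)
  if (length(x0) != n) stop_data("`x0` must have length n_units")

  Tn <- nrow(U)
  X <- matrix(0, Tn, n)
  x <- as.numeric(x0)
  Uin <- U %*% t(res$W_in)   # precompute input projections [T x n_units]
  for (t in seq_len(Tn)) {
    x <- (1 - a) * x + a * tanh(Uin[t, ] + drop(res$W %*% x))
    X[t, ] <- x
  }
  X
}

#' Train a ridge readout on reservoir states
#'
#' Closed-form ridge regression of the (post-washout) states onto binary
#' targets encoded as -1/+1, with an appended bias column excluded from the
#' penalty: \code{W_out = argmin ||t - [X; 1] w||^2 + lambda ||w_-bias||^2}.
#'
#' @param X state (or feature) matrix \code{[T x p]}.
#' @param y binary target vector in {0, 1} (or logical).
#' @param ridge_penalty L2 penalty lambda.
#' @param washout number of leading rows of \code{X} to discard before
#'   fitting (0 for a plain windowed linear readout).
#' @return An object of class \code{esn_readout} holding \code{W_out}
#'   (length p + 1; last entry is the bias) and fitting metadata.
#' @export
fit_readout <- function(X, y, ridge_penalty = 1.0, washout = 0L) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop_data("`X` and `y` must have matching rows")
  if (washout < 0) stop_config("`washout` must be >= 0")
  if (washout >= nrow(X)) stop_degenerate("washout leaves no training rows")
  keep <- (washout + 1L):nrow(X)
  Xk <- X[keep, , drop = FALSE]
  yk <- as.integer(y[keep])
  if (!all(yk %in% c(0L, 1L))) stop_data("targets must be binary (0/1)")
  if (length(unique(yk)) < 2L) {
    stop_degenerate("single-class training targets; fold must be discarded")
  }
  tgt <- 2 * yk - 1
  Z <- cbind(Xk, 1)
  p <- ncol(Xk)
  A <- crossprod(Z) + ridge_penalty * diag(c(rep(1, p), 0))
  w <- solve(A, crossprod(Z, tgt))
  structure(list(W_out = drop(w), ridge_penalty = ridge_penalty,
                 washout = as.integer(washout), n_train = length(yk)),
            class = "esn_readout")
}

#' Score, probability and class from a trained readout
#'
#' Computes the continuous ridge score \code{s = W_out [x; 1]}, maps it
#' through a logistic sigmoid \code{p = 1 / (1 + exp(-s))}, and thresholds the
#' probability at 0.5 (equivalently the score at 0, strict inequality).
#'
#' @param model an [fit_readout()] object.
#' @param X state (or feature) matrix.
#' @return \code{list(score =, prob =, class =)} with \code{class} in {0, 1}.
#' @export
predict_binary <- function(model, X) {
  if (!inherits(model, "esn_readout")) stop_config("`model` must be an esn_readout")
  X <- as.matrix(X)
  if (ncol(X) + 1L != length(model$W_out)) {
    stop_data("state dimension does not match the trained readout")
  }
  s <- drop(cbind(X, 1) %*% model$W_out)
  p <- stats::plogis(s)
  list(score = s, prob = p, class = as.integer(p > 0.5))
}

#' Combine binary valence and arousal predictions into quadrants
#'
#' @param v_pred,a_pred aligned binary prediction vectors.
#' @return Integer quadrant predictions \code{q = 2 v + a}.
#' @export
combine_quadrant <- function(v_pred, a_pred) {
  if (length(v_pred) != length(a_pred)) {
    stop_data("prediction vectors must have equal length")
  }
  quadrant_code(v_pred, a_pred)
}

#' Serialise / restore a reservoir and its readout
#'
#' The archive is plain JSON holding the reservoir configuration (from which
#' \code{W} and \code{W_in} are regenerated deterministically), the number of
#' inputs, and the trained readout weights.
#'
#' @param res a [init_reservoir()] object.
#' @param readout an [fit_readout()] object (optional).
#' @param path file path for the JSON archive.
#' @return \code{write_esn} returns \code{path} invisibly; \code{read_esn}
#'   returns \code{list(reservoir =, readout =)}.
#' @export
write_esn <- function(res, readout = NULL, path) {
  payload <- list(config = unclass(res$config), n_inputs = res$n_inputs)
  if (!is.null(readout)) payload$readout <- unclass(readout)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_esn
#' @export
read_esn <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(reservoir_config, payload$config)
  res <- init_reservoir(cfg, payload$n_inputs)
  readout <- NULL
  if (!is.null(payload$readout)) {
    readout <- structure(payload$readout, class = "esn_readout")
    readout$W_out <- as.numeric(readout$W_out)
  }
  list(reservoir = res, readout = readout)
}
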