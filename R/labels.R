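#' Z-score a numeric series
#'
#' Standardises a series to mean 0 and standard deviation 1 using the
#' population (divide-by-n) standard deviation convention, which this package
#' uses throughout. Optionally applies externally supplied statistics (e.g.
#' from a training fold) instead of the series' own.
#'
#' @param x numeric vector.
#' @param stats optional \code{list(mean =, sd =)} to apply; \code{sd} must be
#'   positive.
#' @return Numeric vector; linear, order-preserving transform of \code{x}.
#' @examples
#' zscore(c(1, 2, 3))   # approximately c(-1.2247, 0, 1.2247)
#' @export
zscore <- function(x, stats = NULL) {
  if (!is.numeric(x)) stop_data("`x` must be numeric")
  if (is.null(stats)) {
    if (length(x) < 2L) stop_degenerate("need at least 2 values to z-score")
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))
    if (s == 0) stop_degenerate("cannot z-score a constant (zero-variance) series")
  } else {
    m <- stats$mean
    s <- stats$sd
    if (is.null(m) || is.null(s) || s <= 0) {
      stop_config("`stats` must supply a finite mean and a positive sd")
    }
  }
  (x - m) / s
}

#' Regress light on temperature and humidity, keep the residual
#'
#' Ordinary least squares of (z-scored) light on temperature and humidity with
#' an intercept. The residual is the component of the light signal that is
#' statistically independent of temperature and humidity within the chamber:
#' it has exactly zero mean and zero sample correlation with both regressors.
#'
#' @param L,T,H numeric vectors of equal length (conventionally z-scored).
#' @return A list with \code{model} (class \code{residual_light_model};
#'   coefficients \code{beta0}, \code{betaT}, \code{betaH} and
#'   \code{r_squared}) and \code{L_res}, the residual series.
#' @export
fit_residual_light <- function(L, T, H) {
  n <- length(L)
  if (length(T) != n || length(H) != n) stop_data("L, T, H must have equal length")
  if (n < 3L) stop_degenerate("need at least 3 samples to fit the light model")
  X <- cbind(`(Intercept)` = 1, T = T, H = H)
  qx <- qr(X)
  if (qx$rank < 3L) {
    keep <- qx$pivot[seq_len(qx$rank)]
    bad <- colnames(X)[setdiff(seq_len(3L), keep)]
    stop_degenerate(paste0("singular light regression; offending regressor(s): ",
                           paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qx, L)
  L_res <- L - drop(X %*% beta)
  denom <- sum((L - mean(L))^2)
  r2 <- if (denom > 0) 1 - sum(L_res^2) / denom else NA_real_
  model <- structure(
    list(beta0 = unname(beta[1]), betaT = unname(beta[2]),
         betaH = unname(beta[3]), r_squared = r2),
    class = "residual_light_model"
  )
  list(model = model, L_res = as.numeric(L_res))
}

#' Valence and arousal coordinates from residual light, temperature, humidity
#'
#' Computes the two environmental affect coordinates as fixed linear
#' combinations on z-scored variables: valence \code{V = L_res - T + H}
#' (favourable: bright residual light, cool, humid) and arousal
#' \code{A = L_res + T - H} (demanding: bright, hot, dry). The identities
#' \code{V + A = 2 L_res} and \code{V - A = 2 (H - T)} hold exactly.
#'
#' @param L_res,T,H numeric vectors of equal length.
#' @return \code{list(V =, A =)}.
#' @export
valence_arousal <- function(L_res, T, H) {
  n <- length(L_res)
  if (length(T) != n || length(H) != n) stop_data("inputs must have equal length")
  list(V = L_res - T + H, A = L_res + T - H)
}

#' Rolling-median smoothing
#'
#' Centered rolling median with an odd window; at the series edges the window
#' shrinks symmetrically (medians of 1, 3, 5, ... points), so the output has
#' the same length as the input. A lone spike inside any window of 3 or more
#' samples is removed entirely.
#'
#' @param x numeric vector.
#' @param window window size in samples; even values are promoted to the next
#'   odd integer.
#' @return Numeric vector of the same length.
#' @export
smooth_series <- function(x, window) {
  if (window < 1) stop_config("`window` must be at least 1 sample")
  k <- as.integer(window)
  if (k %% 2L == 0L) k <- k + 1L
  if (k > length(x)) stop_config("smoothing window longer than the series")
  if (k == 1L) return(as.numeric(x))
  out <- as.numeric(stats::runmed(x, k, endrule = "keep"))
  # symmetric shrinking windows at the edges: medians of 1, 3, 5, ... points
  n <- length(x)
  h <- (k - 1L) %/% 2L
  for (i in seq_len(h)) {
    out[i] <- stats::median(x[1:(2L * i - 1L)])
    out[n - i + 1L] <- stats::median(x[(n - 2L * i + 2L):n])
  }
  out
}

#' Binarise smoothed affect coordinates with a dead-zone
#'
#' Thresholds smoothed valence and arousal at zero (strict inequality) and
#' marks samples falling within \code{deadzone_halfwidth} of either axis as
#' invalid: samples near the regime boundary carry no class.
#'
#' @param V_smooth,A_smooth smoothed coordinate series of equal length.
#' @param deadzone_halfwidth half-width of the exclusion band around zero, in
#'   the (z-unit) scale of the coordinates; 0 disables the dead-zone.
#' @return \code{list(v =, a =, valid =)} with \code{v, a} integer in {0, 1}
#'   and \code{valid} logical.
#' @export
binarize_affect <- function(V_smooth, A_smooth, deadzone_halfwidth = 0.1) {
  n <- length(V_smooth)
  if (length(A_smooth) != n) stop_data("coordinate series must have equal length")
  if (deadzone_halfwidth < 0) stop_config("`deadzone_halfwidth` must be >= 0")
  v <- as.integer(V_smooth > 0)
  a <- as.integer(A_smooth > 0)
  valid <- abs(V_smooth) > deadzone_halfwidth & abs(A_smooth) > deadzone_halfwidth
  list(v = v, a = a, valid = valid)
}

#' Quadrant code from binary valence and arousal
#'
#' Combines the two binary signs into a four-class quadrant label
#' \code{q = 2 v + a}: 0 = (-,-), 1 = (-,+), 2 = (+,-), 3 = (+,+).
#'
#' @param v,a integer/logical vectors with values in {0, 1}.
#' @return Integer vector in {0, 1, 2, 3}.
#' @examples
#' quadrant_code(c(0, 0, 1, 1), c(0, 1, 0, 1))  # 0 1 2 3
#' @export
quadrant_code <- function(v, a) {
  if (length(v) != length(a)) stop_data("`v` and `a` must have equal length")
  v <- as.integer(v)
  a <- as.integer(a)
  ok <- function(x) all(x[!is.na(x)] %in% c(0L, 1L))
  if (!ok(v) || !ok(a)) stop_data("`v` and `a` must be binary (0/1)")
  2L * v + a
}

#' Infrared validity mask
#'
#' Flags samples whose infrared reading is at or above \code{ir_min}. Readings
#' below the threshold correspond to periods when the light/IR sensor failed
#' to report and are excluded jointly from traces and labels.
#'
#' @param env an environment trace with an \code{infrared} column.
#' @param ir_min minimum accepted infrared level (sensor units).
#' @return Logical vector, \code{TRUE} where the sample is kept.
#' @export
ir_filter <- function(env, ir_min = 1) {
  if (!"infrared" %in% names(env)) stop_data("`env` has no infrared channel")
  env$infrared >= ir_min
}

#' Labelling settings
#'
#' @param median_window rolling-median window for the smoothed coordinates,
#'   minutes. The default (15 min) suppresses transients on the scale of
#'   chamber interventions such as lid removal.
#' @param deadzone_halfwidth exclusion half-width around the zero mark of each
#'   smoothed coordinate, z-units.
#' @param ir_min infrared validity threshold, sensor units.
#' @param zscore_scope scope of the label z-scoring statistics. Labels are
#'   external ground truth, so the default uses full-trace statistics;
#'   \code{"train-fold"} is accepted for users who prefer to restrict label
#'   construction to training data (feature standardisation is always
#'   per-fold regardless, see [standardize_per_fold()]).
#' @return An object of class \code{label_config}.
#' @export
label_config <- function(median_window = 15,
                         deadzone_halfwidth = 0.1,
                         ir_min = 1,
                         zscore_scope = c("global", "train-fold")) {
  if (median_window <= 0) stop_config("`median_window` must be positive")
  if (deadzone_halfwidth < 0) stop_config("`deadzone_halfwidth` must be >= 0")
  zscore_scope <- match.arg(zscore_scope)
  structure(list(median_window = median_window,
                 deadzone_halfwidth = deadzone_halfwidth,
                 ir_min = ir_min, zscore_scope = zscore_scope),
            class = "label_config")
}

#' Construct affect labels from an environment trace
#'
#' Full labelling chain: z-score temperature, humidity and light over the
#' trace; regress light on temperature and humidity and keep the residual;
#' form the valence and arousal coordinates; smooth both with a centered
#' rolling median; binarise with a dead-zone; compose the quadrant code; and
#' combine the dead-zone mask with the infrared validity filter. Labels are a
#' pure function of the environment trace and the configuration - internal
#' plant signals never enter label construction.
#'
#' @param env an [simulate_environment()] trace (or any data frame with
#'   \code{timestamp}, \code{temperature}, \code{humidity}, \code{light},
#'   \code{infrared} columns).
#' @param config a [label_config()].
#' @return A data frame of class \code{affect_labels} with columns
#'   \code{timestamp}, \code{L_res}, \code{V}, \code{A}, \code{V_smooth},
#'   \code{A_smooth}, \code{v}, \code{a}, \code{q}, \code{valid}; the fitted
#'   \code{residual_light_model} is stored in \code{attr(, "model")}.
#' @export
affect_labels <- function(env, config = label_config()) {
  need <- c("timestamp", "temperature", "humidity", "light", "infrared")
  if (!all(need %in% names(env))) {
    stop_data(paste("environment trace must contain columns:",
                    paste(need, collapse = ", ")))
  }
  period <- attr(env, "period")
  if (is.null(period)) period <- stats::median(diff(env$timestamp))

  zT <- zscore(env$temperature)
  zH <- zscore(env$humidity)
  zL <- zscore(env$light)
  fit <- fit_residual_light(zL, zT, zH)
  va <- valence_arousal(fit$L_res, zT, zH)

  k <- odd_window_samples(config$median_window, period)
  V_smooth <- smooth_series(va$V, k)
  A_smooth <- smooth_series(va$A, k)

  bin <- binarize_affect(V_smooth, A_smooth, config$deadzone_halfwidth)
  q <- quadrant_code(bin$v, bin$a)
  valid <- bin$valid & ir_filter(env, config$ir_min)

  structure(
    data.frame(timestamp = env$timestamp, L_res = fit$L_res,
               V = va$V, A = va$A, V_smooth = V_smooth, A_smooth = A_smooth,
               v = bin$v, a = bin$a, q = q, valid = valid),
    model = fit$model, config = config, period = period,
    class = c("affect_labels", "data.frame")
  )
}

#' Circularly shift the label columns of an affect-label frame
#'
#' Raw-sample-level counterpart of the window-level shifting used by
#' [run_null()]: rotates every label-derived column (coordinates, smoothed
#' coordinates, binary signs, quadrant and validity mask) by the same number
#' of samples while leaving the timestamps in place, for users who prefer to
#' destroy label alignment before windowing.
#'
#' @param labels an [affect_labels()] frame.
#' @param shift shift in samples, \code{0 <= shift < nrow(labels)}.
#' @return The shifted \code{affect_labels} frame.
#' @export
shift_affect_labels <- function(labels, shift) {
  cols <- c("L_res", "V", "A", "V_smooth", "A_smooth", "v", "a", "q", "valid")
  for (cl in intersect(cols, names(labels))) {
    labels[[cl]] <- circular_shift(labels[[cl]], shift)
  }
  labels
}
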