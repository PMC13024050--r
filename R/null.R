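#' Circular time shift
#'
#' Rotates a sequence so that \code{out[i] = x[(i - shift) mod n]}. Length and
#' class histogram are preserved exactly; a shift of 0 is the identity.
#'
#' @param x vector.
#' @param shift non-negative shift in samples, strictly less than
#'   \code{length(x)}.
#' @return The rotated vector.
#' @export
circular_shift <- function(x, shift) {
  n <- length(x)
  if (shift < 0 || shift >= n) stop_config("`shift` must satisfy 0 <= shift < length(x)")
  if (shift == 0) return(x)
  x[((seq_len(n) - 1L - as.integer(shift)) %% n) + 1L]
}

#' Null-control settings
#'
#' @param min_shift smallest admissible misalignment between labels and
#'   signals, minutes. Must exceed the memory of the coupling under test for
#'   the null to be informative (the recording protocol used tiers of 60 and
#'   360 min for arousal, 360 and 720 min for valence).
#' @param n_permutations number of shifted re-runs.
#' @param seed integer seed for shift sampling.
#' @param scope which labelling the null targets (bookkeeping only).
#' @return An object of class \code{null_spec}.
#' @export
null_spec <- function(min_shift, n_permutations = 50L, seed = 1L,
                      scope = c("valence", "arousal", "quadrant")) {
  if (min_shift <= 0) stop_config("`min_shift` must be positive")
  if (n_permutations < 1L) stop_config("`n_permutations` must be at least 1")
  scope <- match.arg(scope)
  structure(list(min_shift = min_shift,
                 n_permutations = as.integer(n_permutations),
                 seed = seed, scope = scope),
            class = "null_spec")
}

#' Sample admissible circular shifts
#'
#' Draws shifts uniformly from the set of sample offsets that misalign labels
#' by at least \code{min_shift} minutes in both circular directions:
#' \code{{s : s * period >= min_shift and (n - s) * period >= min_shift}}.
#'
#' @param spec a [null_spec()].
#' @param series_length number of samples in the label sequence.
#' @param sample_period seconds between consecutive samples (for window-level
#'   shifting this is the window stride).
#' @return Integer vector of \code{n_permutations} shifts.
#' @export
sample_shifts <- function(spec, series_length, sample_period) {
  if (!inherits(spec, "null_spec")) stop_config("`spec` must be a null_spec")
  min_s <- spec$min_shift * 60
  smin <- as.integer(ceiling(min_s / sample_period))
  smax <- as.integer(floor(series_length - min_s / sample_period))
  if (smin > smax) {
    stop_config("no admissible shifts: `min_shift` exceeds half the circular span")
  }
  with_seed(spec$seed, sample(smin:smax, spec$n_permutations, replace = TRUE))
}

#' Circular-shift permutation null for a decoding task
#'
#' Re-runs the identical decoding protocol with labels circularly shifted
#' relative to the plant signals. Shifting happens at the window level, in
#' units of the window stride, so the feature set is bit-identical across null
#' runs and label alignment is the only difference. Shifts that would leave
#' any training fold with a single class are discarded and resampled, up to a
#' bounded retry budget. (For raw-sample-level shifting before windowing, see
#' [shift_affect_labels()].)
#'
#' @param windows a [make_windows()] table.
#' @param target,decoder,n_splits,ridge_penalty,reservoir as in
#'   [evaluate_pipeline()].
#' @param spec a [null_spec()].
#' @param max_retries total shift draws allowed before returning a partial
#'   result with a warning (default 10x the requested permutations).
#' @return An object of class \code{null_result}: the unshifted fold-mean
#'   balanced accuracy, the vector of null balanced accuracies with the shifts
#'   (in windows and minutes) that produced them, the null mean and sd, the
#'   empirical exceedance fraction \code{P(null >= unshifted)}, and the number
#'   of discarded shifts.
#' @export
run_null <- function(windows, target, spec,
                     decoder = "ridge", n_splits = 5L, ridge_penalty = 1.0,
                     reservoir = reservoir_config(),
                     max_retries = 10L * spec$n_permutations) {
  if (!inherits(spec, "null_spec")) stop_config("`spec` must be a null_spec")
  stride <- attr(windows, "stride_seconds")
  if (is.null(stride)) stop_data("`windows` carries no stride metadata")
  n <- nrow(windows)

  baseline <- evaluate_pipeline(windows, target, decoder, n_splits,
                                ridge_penalty, reservoir)
  ba0 <- unname(baseline$mean["balanced_accuracy"])

  yv <- as.integer(windows$label_v)
  ya <- as.integer(windows$label_a)
  if (length(unique(yv)) < 2L && length(unique(ya)) < 2L) {
    stop_degenerate("labels are constant; every shift would be discarded")
  }
  plan <- forward_chain_splits(n, n_splits)
  shift_ok <- function(s) {
    # a shift is discarded iff some training fold contains a single class
    sv <- circular_shift(yv, s)
    sa <- circular_shift(ya, s)
    relevant <- switch(target,
                       valence = list(sv), arousal = list(sa),
                       quadrant = list(sv, sa))
    all(vapply(plan$splits, function(sp) {
      all(vapply(relevant, function(lab) length(unique(lab[sp$train])) == 2L, TRUE))
    }, TRUE))
  }

  min_s <- spec$min_shift * 60
  smin <- as.integer(ceiling(min_s / stride))
  smax <- as.integer(floor(n - min_s / stride))
  if (smin > smax) {
    stop_config("no admissible shifts: `min_shift` exceeds half the circular span")
  }

  with_seed(spec$seed, {
    kept_shifts <- integer(0)
    null_ba <- numeric(0)
    discarded <- 0L
    draws <- 0L
    while (length(kept_shifts) < spec$n_permutations && draws < max_retries) {
      s <- sample(smin:smax, 1L)
      draws <- draws + 1L
      if (!shift_ok(s)) {
        discarded <- discarded + 1L
        next
      }
      w <- windows
      w$label_v <- circular_shift(yv, s)
      w$label_a <- circular_shift(ya, s)
      w$label_q <- quadrant_code(w$label_v, w$label_a)
      rep_s <- evaluate_pipeline(w, target, decoder, n_splits,
                                 ridge_penalty, reservoir)
      kept_shifts <- c(kept_shifts, s)
      null_ba <- c(null_ba, unname(rep_s$mean["balanced_accuracy"]))
    }
    if (length(kept_shifts) < spec$n_permutations) {
      warning(sprintf(
        "retry budget exhausted: %d of %d permutations completed (%d shifts discarded)",
        length(kept_shifts), spec$n_permutations, discarded), call. = FALSE)
    }
    if (length(kept_shifts) == 0L) {
      stop_degenerate("no admissible shift survived the single-class-fold discard rule")
    }
    structure(list(
      target = target, decoder = decoder, spec = spec,
      shifts_windows = kept_shifts,
      shifts_minutes = kept_shifts * stride / 60,
      null_balanced_accuracy = null_ba,
      null_mean = mean(null_ba),
      null_sd = stats::sd(null_ba),
      unshifted_balanced_accuracy = ba0,
      exceedance = mean(null_ba >= ba0),
      n_discarded = discarded,
      baseline = baseline
    ), class = "null_result")
  })
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf("<null_result> target=%s decoder=%s, %d permutations (min shift %g min)\n",
              x$target, x$decoder, length(x$null_balanced_accuracy),
              x$spec$min_shift))
  cat(sprintf("  unshifted balanced accuracy: %.3f\n", x$unshifted_balanced_accuracy))
  cat(sprintf("  null: %.3f +/- %.3f | exceedance %.3f | %d shifts discarded\n",
              x$null_mean, x$null_sd, x$exceedance, x$n_discarded))
  invisible(x)
}
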