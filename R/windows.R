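#' Sliding-window settings
#'
#' @param window_min window length, minutes.
#' @param stride_min stride between window starts, minutes; must be positive
#'   and no longer than the window (overlap allowed).
#' @param min_valid_fraction minimum fraction of in-window samples that must
#'   be unmasked for the window to be labelled.
#' @param label_rule how per-sample binary labels are aggregated into a window
#'   label: \code{"majority"} (majority vote over unmasked samples, exact ties
#'   dropped) or \code{"mean-sign"} (sign of the mean smoothed coordinate).
#' @return An object of class \code{window_spec}.
#' @export
window_spec <- function(window_min, stride_min = window_min,
                        min_valid_fraction = 0.5,
                        label_rule = c("majority", "mean-sign")) {
  if (window_min <= 0) stop_config("`window_min` must be positive")
  if (stride_min <= 0 || stride_min > window_min) {
    stop_config("`stride_min` must satisfy 0 < stride <= window length")
  }
  if (min_valid_fraction < 0 || min_valid_fraction > 1) {
    stop_config("`min_valid_fraction` must be in [0, 1]")
  }
  label_rule <- match.arg(label_rule)
  structure(list(window_min = window_min, stride_min = stride_min,
                 min_valid_fraction = min_valid_fraction,
                 label_rule = label_rule),
            class = "window_spec")
}

#' Segment aligned plant signals and labels into a window table
#'
#' Tiles the common timebase of a plant trace and an affect-label frame with
#' half-open windows \code{[start, start + window)} at the configured stride,
#' anchored at the first sample; if the strided grid leaves an uncovered tail,
#' one extra window anchored at the end of the trace is appended. Each
#' window's features are the mean and (population) standard deviation of every
#' plant channel over the unmasked in-window samples; window labels aggregate
#' the unmasked per-sample binary labels under the configured rule. Windows
#' that fail \code{min_valid_fraction}, or whose majority vote is tied, are
#' dropped.
#'
#' @param plant a [simulate_plant()] trace (or data frame with
#'   \code{timestamp}, \code{bioelectric}, \code{eco2}, \code{tvoc}).
#' @param labels an [affect_labels()] frame on the same timebase.
#' @param spec a [window_spec()].
#' @return A data frame of class \code{window_table} with one row per retained
#'   window: \code{window_start}/\code{window_end} (seconds),
#'   \code{n_samples}, \code{n_valid}, six feature columns
#'   (\code{<channel>_mean}, \code{<channel>_sd}), window-mean coordinates
#'   \code{V_mean}/\code{A_mean} (label-derived, for trajectory plots - never
#'   part of the feature set), and labels \code{label_v}, \code{label_a},
#'   \code{label_q}. Feature column names are stored in
#'   \code{attr(, "feature_cols")}, the stride in seconds in
#'   \code{attr(, "stride_seconds")}.
#' @export
make_windows <- function(plant, labels, spec) {
  if (!inherits(spec, "window_spec")) stop_config("`spec` must be a window_spec")
  channels <- intersect(c("bioelectric", "eco2", "tvoc"), names(plant))
  if (length(channels) == 0L) stop_data("`plant` has no recognised signal channels")

  # align on the common timebase
  if (nrow(plant) != nrow(labels) ||
      max(abs(plant$timestamp - labels$timestamp)) > 1e-9) {
    keep_p <- plant$timestamp %in% labels$timestamp
    if (!any(keep_p)) stop_data("plant trace and labels have no temporal overlap")
    plant <- plant[keep_p, , drop = FALSE]
    labels <- labels[labels$timestamp %in% plant$timestamp, , drop = FALSE]
  }
  n <- nrow(plant)
  tt <- plant$timestamp
  period <- stats::median(diff(tt))

  wlen <- spec$window_min * 60 / period
  wstr <- spec$stride_min * 60 / period
  if (abs(wlen - round(wlen)) > 1e-9 || abs(wstr - round(wstr)) > 1e-9) {
    warning("window or stride is not a multiple of the sample period; rounding",
            call. = FALSE)
  }
  wlen <- max(1L, as.integer(round(wlen)))
  wstr <- max(1L, as.integer(round(wstr)))
  if (wlen > n) stop_data("window longer than the available trace")

  starts <- seq.int(1L, n - wlen + 1L, by = wstr)
  if (starts[length(starts)] + wlen - 1L < n) starts <- c(starts, n - wlen + 1L)

  pmat <- as.matrix(plant[, channels, drop = FALSE])
  out <- vector("list", length(starts))
  for (j in seq_along(starts)) {
    i0 <- starts[j]
    idx <- i0:(i0 + wlen - 1L)
    val <- labels$valid[idx]
    nv <- sum(val)
    if (nv < spec$min_valid_fraction * wlen || nv == 0L) next

    vidx <- idx[val]
    lv <- window_label(labels$v[vidx], labels$V_smooth[vidx], spec$label_rule)
    la <- window_label(labels$a[vidx], labels$A_smooth[vidx], spec$label_rule)
    if (is.na(lv) || is.na(la)) next

    sub <- pmat[vidx, , drop = FALSE]
    mu <- colMeans(sub)
    sd_p <- sqrt(colMeans(sub^2) - mu^2)
    feats <- c(rbind(mu, pmax(0, sd_p)))  # guard tiny negative fp round-off
    names(feats) <- as.vector(rbind(paste0(channels, "_mean"),
                                    paste0(channels, "_sd")))
    out[[j]] <- c(window_start = tt[i0], window_end = tt[i0] + wlen * period,
                  n_samples = wlen, n_valid = nv, feats,
                  V_mean = mean(labels$V_smooth[vidx]),
                  A_mean = mean(labels$A_smooth[vidx]),
                  label_v = lv, label_a = la,
                  label_q = 2L * lv + la)
  }
  rows <- out[!vapply(out, is.null, TRUE)]
  if (length(rows) == 0L) {
    stop_degenerate("no labelled windows survive the validity filters (empty analysis set)")
  }
  wt <- as.data.frame(do.call(rbind, rows))
  structure(
    wt,
    feature_cols = as.vector(rbind(paste0(channels, "_mean"),
                                   paste0(channels, "_sd"))),
    stride_seconds = wstr * period,
    spec = spec, period = period,
    class = c("window_table", "data.frame")
  )
}

# Aggregate per-sample binary labels into one window label; NA means the
# window carries no class (tied majority).
window_label <- function(bits, smooth_vals, rule) {
  if (rule == "mean-sign") {
    m <- mean(smooth_vals)
    if (m == 0) return(NA_integer_)
    return(as.integer(m > 0))
  }
  m <- mean(bits)
  if (m == 0.5) return(NA_integer_)
  as.integer(m > 0.5)
}
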