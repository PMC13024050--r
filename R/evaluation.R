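#' Forward-chaining time-series splits
#'
#' Builds a no-shuffle, time-ordered cross-validation plan: the tail of the
#' series is partitioned into \code{n_splits} contiguous test blocks of equal
#' size (any remainder goes to the earlier folds), and fold k trains on every
#' sample strictly before its test block. Training sets therefore grow across
#' folds and every test index exceeds every train index of its fold.
#'
#' @param n_samples series length.
#' @param n_splits number of folds (default 5).
#' @return An object of class \code{fold_plan}: a list with \code{splits}
#'   (each a \code{list(train =, test =)} of 1-based index vectors),
#'   \code{n_samples}, \code{n_splits}.
#' @export
forward_chain_splits <- function(n_samples, n_splits = 5L) {
  n_samples <- as.integer(n_samples)
  n_splits <- as.integer(n_splits)
  if (n_splits < 1L) stop_config("`n_splits` must be at least 1")
  if (n_samples < n_splits + 1L) {
    stop_config(sprintf("need at least %d samples for %d forward-chaining splits",
                        n_splits + 1L, n_splits))
  }
  init_train <- n_samples %/% (n_splits + 1L)
  if (init_train < 1L) stop_config("too few samples: empty initial training block")
  tail_len <- n_samples - init_train
  sizes <- rep(tail_len %/% n_splits, n_splits)
  rem <- tail_len %% n_splits
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  starts <- init_train + cumsum(c(0L, sizes[-n_splits])) + 1L
  splits <- lapply(seq_len(n_splits), function(k) {
    test <- starts[k]:(starts[k] + sizes[k] - 1L)
    list(train = seq_len(starts[k] - 1L), test = test)
  })
  # anti-leakage contract, asserted before any model ever sees the plan
  for (sp in splits) stopifnot(max(sp$train) < min(sp$test))
  structure(list(splits = splits, n_samples = n_samples, n_splits = n_splits),
            class = "fold_plan")
}

#' Standardise features within a training fold
#'
#' Centers and scales the training block to column mean 0 and (population)
#' standard deviation 1, then applies the training statistics to the test
#' block. Constant training columns are centred only and flagged with a
#' warning.
#'
#' @param train_X,test_X numeric matrices with matching columns.
#' @return \code{list(train =, test =, stats = list(mean =, sd =))}.
#' @export
standardize_per_fold <- function(train_X, test_X) {
  train_X <- as.matrix(train_X)
  test_X <- as.matrix(test_X)
  if (nrow(train_X) < 2L) stop_degenerate("training fold needs at least 2 rows")
  mu <- colMeans(train_X)
  sd_p <- sqrt(colMeans(train_X^2) - mu^2)
  sd_p <- pmax(sd_p, 0)
  const <- sd_p == 0
  if (any(const)) {
    warning(sprintf("constant training column(s) passed through centred: %s",
                    paste(which(const), collapse = ", ")), call. = FALSE)
    sd_p[const] <- 1
  }
  list(train = sweep(sweep(train_X, 2, mu), 2, sd_p, "/"),
       test = sweep(sweep(test_X, 2, mu), 2, sd_p, "/"),
       stats = list(mean = mu, sd = sd_p))
}

#' Confusion matrix over a fixed class set
#'
#' @param true,pred class vectors.
#' @param classes class levels defining row/column order (defaults to the
#'   sorted union of both vectors).
#' @return Integer matrix, rows = true classes, columns = predicted.
#' @export
confusion_matrix <- function(true, pred, classes = sort(unique(c(true, pred)))) {
  if (length(true) != length(pred)) stop_data("`true` and `pred` must match in length")
  tf <- factor(true, levels = classes)
  pf <- factor(pred, levels = classes)
  unclass(table(tf, pf, dnn = c("true", "predicted")))
}

#' Balanced accuracy from a confusion matrix
#'
#' Mean of per-class recalls. Classes with zero true samples are excluded
#' (with a warning unless \code{quiet}); balanced accuracy is therefore
#' invariant to duplicating all samples of any single class.
#'
#' @param cm square count matrix (rows = true classes).
#' @param quiet suppress the zero-class warning.
#' @return A number in [0, 1].
#' @export
balanced_accuracy <- function(cm, quiet = FALSE) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop_data("confusion matrix must be square")
  totals <- rowSums(cm)
  if (any(totals == 0)) {
    if (!quiet) {
      warning(sprintf("class(es) with no true samples excluded from balanced accuracy: %s",
                      paste(rownames(cm)[totals == 0], collapse = ", ")),
              call. = FALSE)
    }
  }
  keep <- totals > 0
  if (!any(keep)) stop_degenerate("no true samples in any class")
  mean(diag(cm)[keep] / totals[keep])
}

#' Per-class and macro-averaged F1 from a confusion matrix
#'
#' Per-class F1 is \code{2PR / (P + R)}, defined as 0 when precision and
#' recall are both undefined or zero; the macro score is their unweighted
#' mean.
#'
#' @param cm square count matrix (rows = true classes).
#' @return \code{list(per_class =, macro =)}.
#' @export
f1_scores <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop_data("confusion matrix must be square")
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  names(f1) <- rownames(cm)
  list(per_class = f1, macro = mean(f1))
}

#' Majority-class baseline
#'
#' @param class_counts vector of per-class counts.
#' @return \code{max(counts) / sum(counts)}.
#' @examples
#' majority_baseline(c(108, 111))    # ~0.51
#' majority_baseline(c(1103, 1823))  # ~0.62
#' @export
majority_baseline <- function(class_counts) {
  if (length(class_counts) == 0L || sum(class_counts) == 0) {
    stop_degenerate("empty class counts")
  }
  max(class_counts) / sum(class_counts)
}

#' Decode window labels under forward-chaining cross-validation
#'
#' Runs the full decoding protocol on a window table: for each fold of a
#' forward-chaining plan, features are standardised on the training block,
#' a decoder is trained on the training block, and predictions are scored on
#' the strictly later test block. Two decoders are available:
#' \describe{
#'   \item{\code{"ridge"}}{the windowed linear decoder - the same ridge score
#'     plus logistic sigmoid readout applied directly to the window features.}
#'   \item{\code{"esn"}}{a fixed random reservoir (shared across folds) driven
#'     by the standardised feature vectors in window order, one step per
#'     window, with a per-fold ridge readout fit on post-washout training
#'     states.}
#' }
#' The quadrant target is decoded by combining independent binary valence and
#' arousal predictions (\code{q = 2v + a}); folds whose training labels are
#' single-class are skipped and reported.
#'
#' @param windows a [make_windows()] table.
#' @param target \code{"valence"}, \code{"arousal"} or \code{"quadrant"}.
#' @param decoder \code{"ridge"} or \code{"esn"}.
#' @param n_splits number of forward-chaining folds.
#' @param ridge_penalty readout penalty for the \code{"ridge"} decoder.
#' @param reservoir a [reservoir_config()] for the \code{"esn"} decoder.
#' @return An object of class \code{metrics_report}: per-fold and pooled
#'   accuracy, balanced accuracy and F1 (binary) or macro-F1, pooled confusion
#'   matrix, majority baseline of the pooled test labels, fold mean +/- sd,
#'   and the set of skipped folds.
#' @export
evaluate_pipeline <- function(windows,
                              target = c("valence", "arousal", "quadrant"),
                              decoder = c("ridge", "esn"),
                              n_splits = 5L,
                              ridge_penalty = 1.0,
                              reservoir = reservoir_config()) {
  target <- match.arg(target)
  decoder <- match.arg(decoder)
  feature_cols <- attr(windows, "feature_cols")
  if (is.null(feature_cols)) stop_data("`windows` carries no feature column metadata")
  forbidden <- c("temperature", "humidity", "light", "infrared", "heater", "fan")
  if (any(vapply(forbidden, function(f) any(grepl(f, feature_cols, fixed = TRUE)), TRUE))) {
    stop_config("environmental channels must never enter the decoder feature set")
  }

  F <- as.matrix(windows[, feature_cols, drop = FALSE])
  yv <- as.integer(windows$label_v)
  ya <- as.integer(windows$label_a)
  y <- switch(target, valence = yv, arousal = ya,
              quadrant = as.integer(windows$label_q))
  if (length(unique(y)) < 2L) {
    stop_degenerate("fewer than 2 classes present overall; nothing to decode")
  }
  classes <- if (target == "quadrant") 0:3 else 0:1

  plan <- forward_chain_splits(nrow(F), n_splits)
  res <- if (decoder == "esn") init_reservoir(reservoir, ncol(F)) else NULL

  fold_rows <- list()
  skipped <- character(0)
  pooled <- matrix(0L, length(classes), length(classes),
                   dimnames = list(true = classes, predicted = classes))

  for (k in seq_along(plan$splits)) {
    sp <- plan$splits[[k]]
    stopifnot(max(sp$train) < min(sp$test))
    train_ok <- if (target == "quadrant") {
      length(unique(yv[sp$train])) == 2L && length(unique(ya[sp$train])) == 2L
    } else {
      length(unique(y[sp$train])) == 2L
    }
    if (!train_ok) {
      skipped <- c(skipped, sprintf("fold %d: single-class training labels", k))
      next
    }

    std <- suppressWarnings(standardize_per_fold(F[sp$train, , drop = FALSE], F))
    Zfull <- std$test          # full series in train-fold coordinates
    if (decoder == "esn") {
      states <- run_reservoir(res, Zfull)
      wash <- reservoir$washout
      pen <- reservoir$ridge_penalty
    } else {
      states <- Zfull
      wash <- 0L
      pen <- ridge_penalty
    }

    pred <- tryCatch({
      if (target == "quadrant") {
        mv <- fit_readout(states[sp$train, , drop = FALSE], yv[sp$train], pen, wash)
        ma <- fit_readout(states[sp$train, , drop = FALSE], ya[sp$train], pen, wash)
        combine_quadrant(predict_binary(mv, states[sp$test, , drop = FALSE])$class,
                         predict_binary(ma, states[sp$test, , drop = FALSE])$class)
      } else {
        m <- fit_readout(states[sp$train, , drop = FALSE], y[sp$train], pen, wash)
        predict_binary(m, states[sp$test, , drop = FALSE])$class
      }
    }, phyto_degenerate_error = function(e) conditionMessage(e))
    if (is.character(pred)) {
      skipped <- c(skipped, sprintf("fold %d: %s", k, pred))
      next
    }

    cm <- confusion_matrix(y[sp$test], pred, classes)
    pooled <- pooled + cm
    f1 <- f1_scores(cm)
    fold_rows[[length(fold_rows) + 1L]] <- data.frame(
      fold = k,
      n_train = length(sp$train),
      n_test = length(sp$test),
      accuracy = sum(diag(cm)) / sum(cm),
      balanced_accuracy = balanced_accuracy(cm, quiet = TRUE),
      f1 = if (target == "quadrant") NA_real_ else f1$per_class["1"],
      macro_f1 = f1$macro
    )
  }

  if (length(fold_rows) == 0L) {
    stop_degenerate("all folds skipped (single-class training labels throughout)")
  }
  folds <- do.call(rbind, fold_rows)
  rownames(folds) <- NULL
  pooled_f1 <- f1_scores(pooled)
  counts <- as.integer(table(factor(y, levels = classes)))

  structure(list(
    target = target, decoder = decoder,
    n_windows = nrow(F), class_counts = stats::setNames(counts, classes),
    folds = folds,
    mean = vapply(folds[c("accuracy", "balanced_accuracy", "f1", "macro_f1")],
                  mean, 0),
    sd = vapply(folds[c("accuracy", "balanced_accuracy", "f1", "macro_f1")],
                stats::sd, 0),
    pooled = list(confusion = pooled,
                  accuracy = sum(diag(pooled)) / sum(pooled),
                  balanced_accuracy = balanced_accuracy(pooled, quiet = TRUE),
                  f1 = if (target == "quadrant") NA_real_ else pooled_f1$per_class["1"],
                  macro_f1 = pooled_f1$macro),
    majority_baseline = majority_baseline(rowSums(pooled)),
    skipped = skipped
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> target=%s decoder=%s windows=%d\n",
              x$target, x$decoder, x$n_windows))
  cat(sprintf("  fold-mean balanced accuracy: %.3f +/- %.3f (accuracy %.3f, macro-F1 %.3f)\n",
              x$mean["balanced_accuracy"], x$sd["balanced_accuracy"],
              x$mean["accuracy"], x$mean["macro_f1"]))
  cat(sprintf("  pooled balanced accuracy:    %.3f | majority baseline %.2f\n",
              x$pooled$balanced_accuracy, x$majority_baseline))
  if (length(x$skipped)) cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}
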