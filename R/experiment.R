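#' Full experiment configuration
#'
#' Bundles every stage configuration into one reproducible object. The window
#' plans default to the task-specific choices of the decoding protocol:
#' valence at 20 min windows / 15 min stride, arousal at 1 min windows,
#' combined-binary quadrant decoding on the 20/15 table, the trajectory table
#' at non-overlapping 7 min windows, and the ESN on 1 min windows (the finer
#' windowing that gives the reservoir a long, temporally continuous input
#' sequence).
#'
#' @param chamber a [chamber_config()].
#' @param coupling a [coupling_config()].
#' @param labels a [label_config()].
#' @param windows named list of [window_spec()]s with entries \code{valence},
#'   \code{arousal}, \code{trajectory}, \code{esn}.
#' @param reservoir a [reservoir_config()].
#' @param n_splits forward-chaining folds.
#' @param n_permutations permutations per null tier.
#' @param null_shifts named list of minimum-shift tiers in minutes, one vector
#'   per target.
#' @param feature_channels plant channels the decoders may see; listing an
#'   environmental channel here is refused at validation.
#' @param seed global seed; stage seeds derive from it deterministically.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(chamber = chamber_config(),
                       coupling = coupling_config(),
                       labels = label_config(),
                       windows = list(valence = window_spec(20, 15),
                                      arousal = window_spec(1, 1),
                                      trajectory = window_spec(7, 7),
                                      esn = window_spec(1, 1)),
                       reservoir = reservoir_config(),
                       n_splits = 5L,
                       n_permutations = 20L,
                       null_shifts = list(arousal = c(60, 360),
                                          valence = c(360, 720)),
                       feature_channels = c("bioelectric", "eco2", "tvoc"),
                       seed = 1L) {
  allowed <- c("bioelectric", "eco2", "tvoc")
  bad <- setdiff(feature_channels, allowed)
  if (length(bad) > 0L) {
    stop_config(paste0("refused: non-plant channel(s) in the decoder feature set: ",
                       paste(bad, collapse = ", ")))
  }
  need <- c("valence", "arousal", "trajectory", "esn")
  if (!all(need %in% names(windows))) {
    stop_config(paste("`windows` must provide specs named:",
                      paste(need, collapse = ", ")))
  }
  structure(list(chamber = chamber, coupling = coupling, labels = labels,
                 windows = windows, reservoir = reservoir,
                 n_splits = as.integer(n_splits),
                 n_permutations = as.integer(n_permutations),
                 null_shifts = null_shifts,
                 feature_channels = feature_channels,
                 seed = seed),
            class = "run_config")
}

#' Run the full decoding experiment
#'
#' Executes the whole chain on synthetic data: simulate the chamber, simulate
#' the plant, construct labels, window, decode valence (windowed linear),
#' arousal (windowed linear, short windows), quadrant (combined binaries and
#' ESN), and run the circular-shift null tiers. A hard guard enforces that no
#' environmental channel ever enters a decoder feature set. When
#' \code{out_dir} is given, writes \code{metrics.json}, per-task confusion
#' CSVs, the valence-arousal trajectory table, the configuration YAML, and a
#' plain-text log; the JSON is byte-identical across runs of the same
#' configuration.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return A report bundle: \code{list(config, metrics, nulls, trajectory,
#'   log)}, invisibly when \code{out_dir} is given.
#' @export
run_experiment <- function(config = run_config(), out_dir = NULL, quiet = FALSE) {
  if (!inherits(config, "run_config")) stop_config("`config` must be a run_config")
  log <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    if (!quiet) message(line)
    invisible(NULL)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        class = c(class(e)[1], "error", "condition")))
    })
  }

  # feature-provenance guard (also re-checked inside evaluate_pipeline)
  env_channels <- c("temperature", "humidity", "light", "infrared", "heater", "fan")
  if (any(config$feature_channels %in% env_channels)) {
    stop_config("refused: environmental channels cannot be decoder features")
  }

  say("simulate: chamber %g h at %g Hz (seed %s)",
      config$chamber$duration_hours, config$chamber$env_rate,
      format(config$seed))
  chamber <- config$chamber; chamber$seed <- config$seed
  coupling <- config$coupling; coupling$seed <- config$seed + 1
  env <- stage("simulate", simulate_environment(chamber))
  plant <- stage("simulate", simulate_plant(env, coupling))
  plant <- plant[, c("timestamp", config$feature_channels), drop = FALSE]

  say("label: median window %g min, dead-zone %.2f, IR >= %g",
      config$labels$median_window, config$labels$deadzone_halfwidth,
      config$labels$ir_min)
  labels <- stage("label", affect_labels(env, config$labels))
  say("label: %.1f%% of samples valid", 100 * mean(labels$valid))

  wt <- lapply(config$windows, function(spec) {
    stage("windows", make_windows(plant, labels, spec))
  })
  for (nm in names(wt)) {
    say("windows[%s]: %d labelled windows (%g min / %g min stride)",
        nm, nrow(wt[[nm]]), config$windows[[nm]]$window_min,
        config$windows[[nm]]$stride_min)
  }

  res_cfg <- config$reservoir; res_cfg$seed <- config$seed + 2
  metrics <- list(
    valence = stage("decode-linear",
                    evaluate_pipeline(wt$valence, "valence", "ridge", config$n_splits)),
    arousal = stage("decode-linear",
                    evaluate_pipeline(wt$arousal, "arousal", "ridge", config$n_splits)),
    arousal_long_window = stage("decode-linear",
                                evaluate_pipeline(wt$valence, "arousal", "ridge",
                                                  config$n_splits)),
    quadrant_combined = stage("decode-linear",
                              evaluate_pipeline(wt$valence, "quadrant", "ridge",
                                                config$n_splits)),
    quadrant_esn = stage("decode-esn",
                         evaluate_pipeline(wt$esn, "quadrant", "esn", config$n_splits,
                                           reservoir = res_cfg))
  )
  for (nm in names(metrics)) {
    m <- metrics[[nm]]
    say("decode[%s]: balanced accuracy %.3f +/- %.3f (baseline %.2f)%s",
        nm, m$mean["balanced_accuracy"],
        if (is.na(m$sd["balanced_accuracy"])) 0 else m$sd["balanced_accuracy"],
        m$majority_baseline,
        if (length(m$skipped)) sprintf(" [%d fold(s) skipped]", length(m$skipped)) else "")
  }

  nulls <- list()
  for (tgt in names(config$null_shifts)) {
    for (ms in config$null_shifts[[tgt]]) {
      key <- sprintf("%s_%gmin", tgt, ms)
      tab <- if (tgt == "valence") wt$valence else wt$arousal
      spec <- null_spec(ms, config$n_permutations, seed = config$seed + 3, scope = tgt)
      nulls[[key]] <- stage("null", run_null(tab, tgt, spec, n_splits = config$n_splits))
      say("null[%s]: null %.3f +/- %.3f vs unshifted %.3f (%d discarded)",
          key, nulls[[key]]$null_mean, nulls[[key]]$null_sd,
          nulls[[key]]$unshifted_balanced_accuracy, nulls[[key]]$n_discarded)
    }
  }

  trajectory <- data.frame(
    window_index = seq_len(nrow(wt$trajectory)),
    window_start = wt$trajectory$window_start,
    V_mean = wt$trajectory$V_mean,
    A_mean = wt$trajectory$A_mean,
    quadrant = wt$trajectory$label_q
  )
  say("trajectory: %d windows, quadrant occupancy %s",
      nrow(trajectory),
      paste(names(table(trajectory$quadrant)), as.integer(table(trajectory$quadrant)),
            sep = ":", collapse = " "))

  bundle <- list(config = config, metrics = metrics, nulls = nulls,
                 trajectory = trajectory, log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    to_json <- list(
      metrics = lapply(metrics, function(m) list(
        target = m$target, decoder = m$decoder, n_windows = m$n_windows,
        class_counts = as.list(m$class_counts),
        fold_mean = as.list(m$mean), fold_sd = as.list(m$sd),
        pooled = list(accuracy = m$pooled$accuracy,
                      balanced_accuracy = m$pooled$balanced_accuracy,
                      macro_f1 = m$pooled$macro_f1),
        majority_baseline = m$majority_baseline,
        skipped = m$skipped)),
      nulls = lapply(nulls, function(nr) list(
        min_shift_minutes = nr$spec$min_shift,
        n_permutations = length(nr$null_balanced_accuracy),
        null_mean = nr$null_mean, null_sd = nr$null_sd,
        unshifted = nr$unshifted_balanced_accuracy,
        exceedance = nr$exceedance, discarded = nr$n_discarded))
    )
    jsonlite::write_json(to_json, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in names(metrics)) {
      utils::write.csv(metrics[[nm]]$pooled$confusion,
                       file.path(out_dir, sprintf("confusion_%s.csv", nm)))
    }
    utils::write.csv(trajectory, file.path(out_dir, "trajectory.csv"),
                     row.names = FALSE)
    write_run_config(config, file.path(out_dir, "config.yaml"))
    writeLines(log, file.path(out_dir, "run.log"))
    return(invisible(bundle))
  }
  bundle
}
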