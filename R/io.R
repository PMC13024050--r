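#' Write a trace to tidy CSV
#'
#' Schemas: environment traces use the header
#' \code{timestamp,temperature,humidity,light,infrared,heater,fan}; plant
#' traces use \code{timestamp,bioelectric,eco2,tvoc}. Numeric values are
#' written with 17 significant digits so a write/read cycle reproduces the
#' trace exactly; timestamps are epoch/relative seconds by default or ISO-8601
#' UTC strings on request.
#'
#' @param trace an \code{environment_trace} or \code{plant_trace}.
#' @param path output file.
#' @param timestamps \code{"seconds"} or \code{"iso8601"}.
#' @param origin POSIXct origin used when formatting ISO-8601 timestamps.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(trace, path, timestamps = c("seconds", "iso8601"),
                            origin = as.POSIXct("2026-01-01", tz = "UTC")) {
  timestamps <- match.arg(timestamps)
  df <- as.data.frame(trace)
  cols <- lapply(names(df), function(nm) {
    x <- df[[nm]]
    if (nm == "timestamp" && timestamps == "iso8601") {
      format(origin + x, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
    } else if (nm %in% c("heater", "fan")) {
      as.character(as.integer(x))
    } else {
      sprintf("%.17g", x)
    }
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trace from CSV
#'
#' Validates the header against the schema, parses timestamps (numeric
#' seconds or ISO-8601), requires strictly increasing time, reports the first
#' malformed row by line number, and flags sampling gaps larger than twice the
#' nominal period with a warning.
#'
#' @param path CSV file.
#' @param schema \code{"environment"} or \code{"plant"}.
#' @return A typed trace data frame (\code{environment_trace} or
#'   \code{plant_trace}) with relative-seconds timestamps.
#' @export
read_trace_csv <- function(path, schema = c("environment", "plant")) {
  schema <- match.arg(schema)
  expected <- if (schema == "environment") {
    c("timestamp", "temperature", "humidity", "light", "infrared", "heater", "fan")
  } else {
    c("timestamp", "bioelectric", "eco2", "tvoc")
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(df), expected)) {
    stop_data(sprintf("header mismatch: expected '%s', found '%s'",
                      paste(expected, collapse = ","),
                      paste(names(df), collapse = ",")))
  }
  if (nrow(df) == 0L) stop_data("trace file contains no rows")

  ts_raw <- df$timestamp
  ts <- suppressWarnings(as.numeric(ts_raw))
  if (anyNA(ts)) {
    parsed <- as.POSIXct(ts_raw, tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                        "%Y-%m-%d %H:%M:%OS"))
    if (anyNA(parsed)) {
      stop_data(sprintf("unparseable timestamp at line %d: '%s'",
                        which(is.na(parsed))[1] + 1L, ts_raw[which(is.na(parsed))[1]]))
    }
    ts <- as.numeric(parsed) - as.numeric(parsed[1])
  }
  for (nm in setdiff(expected, "timestamp")) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (anyNA(v)) {
      stop_data(sprintf("malformed value in column '%s' at line %d: '%s'",
                        nm, which(is.na(v))[1] + 1L, df[[nm]][which(is.na(v))[1]]))
    }
    df[[nm]] <- v
  }
  df$timestamp <- ts
  if (any(diff(ts) <= 0)) {
    stop_data(sprintf("timestamps are not strictly increasing at line %d",
                      which(diff(ts) <= 0)[1] + 2L))
  }
  period <- stats::median(diff(ts))
  gaps <- which(diff(ts) > 2 * period)
  if (length(gaps) > 0L) {
    warning(sprintf("%d sampling gap(s) larger than twice the nominal period (first at line %d)",
                    length(gaps), gaps[1] + 2L), call. = FALSE)
  }
  cls <- if (schema == "environment") "environment_trace" else "plant_trace"
  structure(df, period = period, class = c(cls, "data.frame"))
}

#' Write / read a run configuration as YAML
#'
#' Flat key-value serialisation of a [run_config()]; a run is reproducible
#' from its configuration file alone.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return \code{write_run_config} returns \code{path} invisibly;
#'   \code{read_run_config} returns the reconstructed \code{run_config}.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  yaml::write_yaml(strip(unclass(config)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ws <- function(x) do.call(window_spec, x)
  run_config(
    chamber = do.call(chamber_config, raw$chamber),
    coupling = do.call(coupling_config, raw$coupling),
    labels = do.call(label_config, raw$labels),
    windows = lapply(raw$windows, ws),
    reservoir = do.call(reservoir_config, raw$reservoir),
    n_splits = raw$n_splits,
    n_permutations = raw$n_permutations,
    null_shifts = raw$null_shifts,
    feature_channels = raw$feature_channels,
    seed = raw$seed
  )
}
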