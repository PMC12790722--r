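#' Write a recording to CSV with a JSON metadata sidecar
#'
#' The interchange dialect is a CSV event table with header
#' `channel,time_s` plus a JSON sidecar `<path>.meta.json` carrying
#' `duration_s`, `n_rows`, `n_cols`, `pitch_um` and `label`.
#'
#' @param set A [spike_train_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(set, path) {
  stopifnot(inherits(set, "spike_train_set"))
  ev <- set$events
  names(ev) <- c("channel", "time_s")
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  meta <- list(duration_s = set$duration,
               n_rows = set$geometry$n_rows,
               n_cols = set$geometry$n_cols,
               pitch_um = set$geometry$pitch,
               label = set$label)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording from CSV (+ JSON sidecar)
#'
#' Reads the dialect written by [write_recording()]. Malformed or
#' out-of-range rows are reported with their line number. Geometry and
#' duration come from the sidecar unless supplied explicitly.
#'
#' @param path CSV path with `channel,time_s` header.
#' @param geometry,duration,label Override the sidecar (all three
#'   required if no sidecar exists).
#' @return A [spike_train_set()].
#' @export
read_recording <- function(path, geometry = NULL, duration = NULL,
                           label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta_path <- paste0(path, ".meta.json")
  if (is.null(geometry) || is.null(duration)) {
    if (!file.exists(meta_path))
      stop("no metadata sidecar at ", meta_path,
           "; supply geometry and duration explicitly")
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (is.null(geometry))
      geometry <- grid_geometry(meta$n_rows, meta$n_cols, meta$pitch_um)
    if (is.null(duration)) duration <- meta$duration_s
    if (is.null(label)) label <- meta$label
  }
  if (is.null(label)) label <- ""
  ev <- utils::read.csv(path, colClasses = c("integer", "numeric"))
  if (!identical(names(ev), c("channel", "time_s")))
    stop("expected header 'channel,time_s', found: ",
         paste(names(ev), collapse = ","))
  bad <- which(is.na(ev$channel) | is.na(ev$time_s))
  if (length(bad))
    stop("malformed row at line ", bad[1L] + 1L, " of ", path)
  n <- n_channels(geometry)
  bad <- which(ev$channel < 1L | ev$channel > n)
  if (length(bad))
    stop("line ", bad[1L] + 1L, ": channel ", ev$channel[bad[1L]],
         " outside geometry [1, ", n, "]")
  bad <- which(ev$time_s < 0 | ev$time_s >= duration)
  if (length(bad))
    stop("line ", bad[1L] + 1L, ": time ", format(ev$time_s[bad[1L]]),
         " outside [0, duration)")
  spike_train_set(ev$channel, ev$time_s, duration, geometry, label)
}

#' Serialize synthetic ground truth as a JSON sidecar
#'
#' Writes the planted structure of a synthetic recording (NB times and
#' origins, planted pairs, generator parameters) next to the recording
#' it belongs to. Function-valued elements (planted response kernels)
#' are recorded by name only.
#'
#' @param truth A `synthetic_ground_truth` from one of the generators.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_ground_truth"))
  x <- unclass(truth)
  is_fun <- vapply(x, is.function, logical(1))
  x[is_fun] <- lapply(names(x)[is_fun], function(nm)
    paste0("<function: ", nm, ">"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read/write a stimulation session's pulse protocol
#'
#' The session interchange format is the recording CSV dialect plus a
#' JSON protocol file `{"pulse_times_s": [...], "stim_channels": [...]}`.
#'
#' @param session A [stimulation_session()].
#' @param csv_path Recording CSV path (written via [write_recording()]).
#' @param json_path Protocol JSON path (default `<csv_path>.session.json`).
#' @return `write_stim_session()` returns `json_path` invisibly;
#'   `read_stim_session()` returns a [stimulation_session()].
#' @export
write_stim_session <- function(session, csv_path,
                               json_path = paste0(csv_path, ".session.json")) {
  stopifnot(inherits(session, "stimulation_session"))
  write_recording(session$spikes, csv_path)
  jsonlite::write_json(list(pulse_times_s = session$pulse_times,
                            stim_channels = session$stim_channels,
                            window_s = session$window),
                       json_path, auto_unbox = FALSE, digits = NA)
  invisible(json_path)
}

#' @rdname write_stim_session
#' @export
read_stim_session <- function(csv_path,
                              json_path = paste0(csv_path, ".session.json")) {
  spikes <- read_recording(csv_path)
  proto <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  stimulation_session(spikes, proto$pulse_times_s,
                      as.integer(proto$stim_channels),
                      window = if (!is.null(proto$window_s))
                        proto$window_s[1L] else 0.15)
}

#' Read an analysis configuration from YAML
#'
#' Reads per-module parameter blocks (`metrics`, `netbursts`,
#' `connectivity`, `stim`, `eisim`, `synth`) plus the global keys `seed`
#' and `out_dir`; unknown top-level keys are rejected so typos never pass
#' silently.
#'
#' @param path YAML file path.
#' @return A named list (class `analysis_config`).
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  allowed <- c("metrics", "netbursts", "connectivity", "stim", "eisim",
               "synth", "seed", "out_dir")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  structure(cfg, class = "analysis_config")
}
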