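#' Run the longitudinal analysis pipeline over recordings
#'
#' Executes per-channel metrics, network-burst detection and
#' functional-connectivity analysis over one or many recordings (e.g. a
#' days-in-vitro series across culture conditions), returning one summary
#' row per recording plus a longitudinal aggregate (metric by condition
#' by timepoint, mean and SEM across replicates). With an `out_dir`, the
#' tables are written as CSV together with a JSON run manifest recording
#' the parameters and output paths.
#'
#' @param recordings List of [spike_train_set()] objects (or CSV paths
#'   readable by [read_recording()]).
#' @param conditions,timepoints Optional vectors (recycled checks apply)
#'   labelling each recording; conditions default to the sets' labels,
#'   timepoints to the recording index.
#' @param params Named list of per-module parameter overrides: elements
#'   `metrics`, `netbursts`, `connectivity` are passed as arguments to
#'   [summarize_channels()], [detect_network_bursts()] and
#'   [pairwise_correlation()]/[build_graph()].
#' @param connectivity Set `FALSE` to skip the (quadratic-cost)
#'   connectivity stage.
#' @param out_dir Optional output directory.
#' @return A `run_manifest`: list with `summary` (per-recording data
#'   frame), `longitudinal` (aggregate data frame), `params`, `paths`,
#'   `started`, `finished`.
#' @export
run_pipeline <- function(recordings, conditions = NULL, timepoints = NULL,
                         params = list(), connectivity = TRUE,
                         out_dir = NULL) {
  started <- Sys.time()
  if (inherits(recordings, "spike_train_set")) recordings <- list(recordings)
  recordings <- lapply(recordings, function(r)
    if (is.character(r)) read_recording(r) else r)
  stopifnot(all(vapply(recordings, inherits, logical(1), "spike_train_set")))
  nrec <- length(recordings)
  if (is.null(conditions))
    conditions <- vapply(recordings, function(r) r$label, character(1))
  if (is.null(timepoints)) timepoints <- seq_len(nrec)
  stopifnot(length(conditions) == nrec, length(timepoints) == nrec)
  unknown <- setdiff(names(params), c("metrics", "netbursts", "connectivity"))
  if (length(unknown))
    stop("unknown params block(s): ", paste(unknown, collapse = ", "))

  rows <- vector("list", nrec)
  for (i in seq_len(nrec)) {
    set <- recordings[[i]]
    cs <- do.call(summarize_channels,
                  c(list(set = set), params$metrics))
    nbs <- do.call(detect_network_bursts,
                   c(list(set = set), params$netbursts))
    nn <- nl <- NA_integer_
    if (isTRUE(connectivity) && cs$aggregates$n_active >= 2) {
      cp <- params$connectivity
      thr <- if (!is.null(cp$threshold)) cp$threshold else 0.3
      cp$threshold <- NULL
      cm <- do.call(pairwise_correlation, c(list(set = set), cp))
      fg <- build_graph(cm, threshold = thr)
      nn <- fg$n_nodes; nl <- fg$n_links
    }
    act <- cs$channels$is_active
    rows[[i]] <- data.frame(
      recording = i, condition = conditions[i], timepoint = timepoints[i],
      n_spikes = n_spikes(set),
      n_active = cs$aggregates$n_active,
      mfr = mean(cs$channels$mfr[act]),
      pct_bursting = cs$aggregates$pct_bursting_electrodes,
      mbr = cs$aggregates$mbr, mbd = cs$aggregates$mbd,
      pct_random_spikes = cs$aggregates$pct_random_spikes,
      nbr = network_burst_rate(nbs),
      nbd = network_burst_duration(nbs),
      n_nodes = nn, n_links = nl)
  }
  summary <- do.call(rbind, rows)

  metric_cols <- setdiff(names(summary),
                         c("recording", "condition", "timepoint"))
  grp <- interaction(summary$condition, summary$timepoint, drop = TRUE)
  longi <- do.call(rbind, lapply(levels(grp), function(g) {
    s <- summary[grp == g, , drop = FALSE]
    do.call(rbind, lapply(metric_cols, function(m) {
      v <- s[[m]][is.finite(s[[m]])]
      data.frame(condition = s$condition[1L], timepoint = s$timepoint[1L],
                 metric = m, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                       else NA_real_)
    }))
  }))
  rownames(longi) <- NULL

  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p1 <- file.path(out_dir, "summary.csv")
    p2 <- file.path(out_dir, "longitudinal.csv")
    utils::write.csv(summary, p1, row.names = FALSE)
    utils::write.csv(longi, p2, row.names = FALSE)
    paths <- c(summary = p1, longitudinal = p2)
  }
  finished <- Sys.time()
  manifest <- structure(list(summary = summary, longitudinal = longi,
                             params = params, paths = paths,
                             started = started, finished = finished),
                        class = "run_manifest")
  if (!is.null(out_dir)) {
    mp <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(
      list(params = params, paths = as.list(paths),
           n_recordings = nrec,
           started = format(started), finished = format(finished)),
      mp, auto_unbox = TRUE, digits = NA)
    manifest$paths <- c(paths, manifest = mp)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d recording(s)\n", nrow(x$summary)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
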