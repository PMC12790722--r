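#' Spike-train set: the event table of a recording
#'
#' The central container of the package: an ordered table of spike events
#' `(channel, time)` tied to an electrode grid geometry and a recording
#' duration. Events are stored sorted by time (ties broken by channel id)
#' and every event must satisfy `0 <= time < duration` and reference a
#' channel of the geometry.
#'
#' @param channel Integer vector of channel ids.
#' @param time Numeric vector of spike times in seconds.
#' @param duration Recording duration in seconds (> 0).
#' @param geometry A [grid_geometry()].
#' @param label Free-text condition tag (e.g. "CYC", "80:20").
#' @return A `spike_train_set`: list with elements `events` (data frame
#'   `channel`, `time`), `duration`, `geometry`, `label`.
#' @examples
#' g <- grid_geometry(4, 4)
#' s <- spike_train_set(c(1L, 2L, 1L), c(0.5, 0.2, 1.4), duration = 2, geometry = g)
#' s
#' @export
spike_train_set <- function(channel, time, duration, geometry, label = "") {
  stopifnot(inherits(geometry, "grid_geometry"),
            is.numeric(duration), length(duration) == 1L, duration > 0)
  channel <- as.integer(channel)
  time <- as.numeric(time)
  if (length(channel) != length(time))
    stop("channel and time must have equal length")
  n <- n_channels(geometry)
  if (length(channel)) {
    bad <- which(channel < 1L | channel > n)
    if (length(bad))
      stop("event ", bad[1L], ": channel ", channel[bad[1L]],
           " outside geometry [1, ", n, "]")
    bad <- which(time < 0 | time >= duration)
    if (length(bad))
      stop("event ", bad[1L], ": time ", format(time[bad[1L]]),
           " outside [0, duration)")
    o <- order(time, channel)
    channel <- channel[o]
    time <- time[o]
  }
  structure(list(events = data.frame(channel = channel, time = time),
                 duration = as.numeric(duration),
                 geometry = geometry,
                 label = as.character(label)[1L]),
            class = "spike_train_set")
}

#' @rdname spike_train_set
#' @param set A `spike_train_set`.
#' @export
n_spikes <- function(set) {
  stopifnot(inherits(set, "spike_train_set"))
  nrow(set$events)
}

#' Merge spike events from several sets sharing a geometry
#'
#' Events are pooled and re-sorted; the duration is the maximum of the
#' parts (all sets must use the same geometry).
#'
#' @param ... `spike_train_set` objects.
#' @param label Label for the merged set.
#' @return A `spike_train_set`.
#' @export
merge_spike_trains <- function(..., label = "") {
  sets <- list(...)
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1), "spike_train_set")))
  g <- sets[[1L]]$geometry
  for (s in sets)
    if (!identical(s$geometry, g)) stop("geometries differ")
  spike_train_set(
    channel = unlist(lapply(sets, function(s) s$events$channel)),
    time = unlist(lapply(sets, function(s) s$events$time)),
    duration = max(vapply(sets, function(s) s$duration, numeric(1))),
    geometry = g, label = label)
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> %d events, %g s, %d x %d grid%s\n",
              nrow(x$events), x$duration,
              x$geometry$n_rows, x$geometry$n_cols,
              if (nzchar(x$label)) paste0(", label \"", x$label, "\"") else ""))
  invisible(x)
}

#' @export
as.data.frame.spike_train_set <- function(x, ...) x$events

#' Raster and array-rate plot of a recording
#'
#' Top panel: spike raster (one row per channel); bottom panel: array-wide
#' firing rate from [array_firing_rate()].
#'
#' @param x A `spike_train_set`.
#' @param bin Bin width in seconds for the rate panel.
#' @param max_points Raster events are subsampled beyond this count.
#' @param ... Unused.
#' @export
plot.spike_train_set <- function(x, bin = 0.025, max_points = 2e5, ...) {
  ev <- x$events
  if (nrow(ev) > max_points)
    ev <- ev[sort(sample.int(nrow(ev), max_points)), ]
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(ev$time, ev$channel, pch = ".", xlab = "",
                 ylab = "channel", xlim = c(0, x$duration), main = x$label)
  r <- array_firing_rate(x, bin = bin)
  graphics::plot(r$time, r$rate, type = "l", xlab = "time (s)",
                 ylab = "array rate (spk/s)")
  invisible(x)
}
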