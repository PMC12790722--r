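#' Stimulation session: recording plus pulse protocol
#'
#' Bundles a spike-train set with the stimulation pulse times and the
#' stimulated channel set. Pulse times must be strictly increasing, lie
#' within the recording, and be separated by more than twice the analysis
#' window so that pre-pulse baselines and post-pulse responses never
#' overlap.
#'
#' @param spikes A [spike_train_set()].
#' @param pulse_times Pulse times in seconds, strictly increasing.
#' @param stim_channels Stimulated channel ids.
#' @param window Analysis window length in seconds (default 0.15).
#' @return A `stimulation_session`.
#' @export
stimulation_session <- function(spikes, pulse_times, stim_channels,
                                window = 0.15) {
  stopifnot(inherits(spikes, "spike_train_set"))
  pulse_times <- as.numeric(pulse_times)
  if (is.unsorted(pulse_times, strictly = TRUE))
    stop("pulse times must be strictly increasing")
  if (any(pulse_times < 0 | pulse_times > spikes$duration))
    stop("pulse times must lie within the recording")
  if (length(pulse_times) > 1 && min(diff(pulse_times)) <= 2 * window)
    stop("consecutive pulses must be separated by more than 2x the window")
  n <- n_channels(spikes$geometry)
  stim_channels <- as.integer(stim_channels)
  if (any(stim_channels < 1L | stim_channels > n))
    stop("stim channel outside geometry")
  structure(list(spikes = spikes, pulse_times = pulse_times,
                 stim_channels = stim_channels, window = window),
            class = "stimulation_session")
}

#' @export
print.stimulation_session <- function(x, ...) {
  cat(sprintf("<stimulation_session> %d pulses on %d channel(s), %d spikes\n",
              length(x$pulse_times), length(x$stim_channels),
              n_spikes(x$spikes)))
  invisible(x)
}

#' Evoked-response map with bootstrap confidence intervals
#'
#' For every channel and post-pulse latency bin, the evoked response is
#' the mean over pulses of the post-pulse spike count minus a
#' duration-matched pre-pulse baseline count: the baseline for a bin of
#' width `w` is the count in the `w`-long window immediately before the
#' pulse, so each per-pulse difference is an integer and the comparison
#' never rests on fractional rate rescaling (which makes bootstrap
#' intervals degenerate at low rates). Responses are averaged over the
#' pulse repetitions (25 in the reference protocol) and a bootstrap over
#' pulses yields per-cell percentile confidence intervals; a cell is
#' flagged significant (positive or negative, by the sign of its mean)
#' when its CI excludes 0. Spikes on the stimulated channels within
#' `blank` of each pulse are discarded (artifact blanking).
#'
#' @param session A [stimulation_session()].
#' @param latency_bins Bin edges in seconds within the 5-150 ms window
#'   (default `c(5, 10, 20, 40, 60, 100, 150)/1000`).
#' @param n_resamples Bootstrap resamples (default 1000).
#' @param alpha CI level: `1 - alpha` percentile CI (default 0.05).
#' @param baseline_window Maximum pre-pulse stretch reserved for
#'   baselines in seconds (default 0.145, matching the response window);
#'   each bin uses the width-matched tail of it, ending at the pulse.
#' @param blank Stim-channel blanking interval after each pulse (s).
#' @param channels Channels to analyze (default all).
#' @param seed Integer seed for the bootstrap.
#' @return A `response_map`: list with `channels`, `latency_bins` (edges),
#'   matrices `mean`, `ci_lower`, `ci_upper` (channel x bin),
#'   `significance` (-1/0/+1), `n_pulses`, `params`.
#' @export
evoked_response <- function(session, latency_bins = c(5, 10, 20, 40, 60, 100, 150) / 1000,
                            n_resamples = 1000, alpha = 0.05,
                            baseline_window = 0.145, blank = 0.002,
                            channels = NULL, seed = NULL) {
  stopifnot(inherits(session, "stimulation_session"),
            length(session$pulse_times) >= 2, n_resamples >= 1,
            alpha > 0, alpha < 1)
  edges <- sort(as.numeric(latency_bins))
  if (min(edges) < 0.005 - 1e-12 || max(edges) > 0.150 + 1e-12)
    stop("latency bins must lie within [5, 150] ms post pulse")
  pulses <- session$pulse_times
  if (length(pulses) > 1 &&
      min(diff(pulses)) <= max(edges) + baseline_window)
    stop("pulse windows overlap for the requested bins/baseline")
  ev <- session$spikes$events
  # blanking
  for (p in pulses) {
    drop <- ev$channel %in% session$stim_channels &
      abs(ev$time - p) <= blank
    if (any(drop)) ev <- ev[!drop, , drop = FALSE]
  }
  nch <- n_channels(session$spikes$geometry)
  if (is.null(channels)) channels <- seq_len(nch)
  channels <- as.integer(channels)
  C <- length(channels)
  B <- length(edges) - 1L
  P <- length(pulses)
  widths <- diff(edges)
  if (max(widths) > baseline_window + 1e-12)
    stop("baseline_window must be at least as long as the widest bin")
  chmap <- match(ev$channel, channels)
  sel0 <- !is.na(chmap)
  # delta[p, cell]: cell index = (b - 1) * C + c
  delta <- matrix(0, nrow = P, ncol = C * B)
  for (pi in seq_len(P)) {
    p <- pulses[pi]
    w <- which(sel0 & ev$time >= p - baseline_window & ev$time < p + max(edges))
    tt <- ev$time[w] - p
    cc <- chmap[w]
    bb <- findInterval(tt, edges, left.open = FALSE)
    post <- tt >= edges[1L] & tt < edges[B + 1L]
    if (any(post)) {
      cell <- (pmin(bb[post], B) - 1L) * C + cc[post]
      cnt <- tabulate(cell, nbins = C * B)
    } else cnt <- integer(C * B)
    # width-matched pre-pulse baseline count per bin
    base_cnt <- integer(C * B)
    pre <- which(tt < 0)
    for (b in seq_len(B)) {
      in_b <- pre[tt[pre] >= -widths[b]]
      if (length(in_b))
        base_cnt[(b - 1L) * C + seq_len(C)] <-
          tabulate(cc[in_b], nbins = C)
    }
    delta[pi, ] <- cnt - base_cnt
  }
  m <- colMeans(delta)
  with_seed(seed, {
    idx <- matrix(sample.int(P, n_resamples * P, replace = TRUE),
                  nrow = n_resamples)
    # resample indicator: n_resamples x P counts
    ind <- matrix(0, n_resamples, P)
    for (r in seq_len(n_resamples))
      ind[r, ] <- tabulate(idx[r, ], nbins = P)
    boots <- (ind %*% delta) / P
    ci <- apply(boots, 2L, stats::quantile,
                probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  })
  lo <- matrix(ci[1L, ], C, B)
  hi <- matrix(ci[2L, ], C, B)
  mm <- matrix(m, C, B)
  sig <- matrix(0L, C, B)
  sig[lo > 0] <- 1L
  sig[hi < 0] <- -1L
  dimnames(mm) <- dimnames(lo) <- dimnames(hi) <- dimnames(sig) <-
    list(channels, paste0(round(edges[-(B + 1L)] * 1000), "-",
                          round(edges[-1L] * 1000), "ms"))
  structure(list(channels = channels, latency_bins = edges,
                 mean = mm, ci_lower = lo, ci_upper = hi,
                 significance = sig, n_pulses = P,
                 params = list(alpha = alpha, n_resamples = n_resamples,
                               baseline_window = baseline_window,
                               blank = blank)),
            class = "response_map")
}

#' @export
print.response_map <- function(x, ...) {
  cat(sprintf(paste0("<response_map> %d channels x %d latency bins,",
                     " %d pulses; %d positive / %d negative significant cells\n"),
              length(x$channels), ncol(x$mean), x$n_pulses,
              sum(x$significance == 1L), sum(x$significance == -1L)))
  invisible(x)
}

#' Response-grid heatmaps per latency bin
#'
#' Renders the evoked-response map on the electrode grid, one panel per
#' latency bin, pixel intensity encoding response strength (positive
#' responses in warm colors, suppression in cool).
#'
#' @param x A `response_map` covering every channel of `geometry`.
#' @param geometry The session's [grid_geometry()].
#' @param ... Unused.
#' @export
plot_response_map <- function(x, geometry, ...) {
  stopifnot(inherits(x, "response_map"),
            length(x$channels) == n_channels(geometry))
  B <- ncol(x$mean)
  op <- graphics::par(mfrow = grDevices::n2mfrow(B), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  lim <- max(abs(x$mean), 1e-9)
  cols <- grDevices::hcl.colors(101, "Blue-Red 2")
  for (b in seq_len(B)) {
    z <- matrix(x$mean[, b], nrow = geometry$n_cols)[, geometry$n_rows:1]
    graphics::image(z, zlim = c(-lim, lim), col = cols, axes = FALSE,
                    main = colnames(x$mean)[b])
  }
  invisible(x)
}

#' Global response curve over latency
#'
#' Sums the positively significant evoked counts over channels per
#' latency bin and normalizes the bins to sum to 1: the average fraction
#' of evoked spikes arriving in each latency range after the stimulus.
#'
#' @param map A `response_map` from [evoked_response()].
#' @return Numeric vector, one fraction per latency bin (sums to 1), or
#'   all zeros with a warning if no positive responses exist.
#' @export
global_response_curve <- function(map) {
  stopifnot(inherits(map, "response_map"))
  pos <- map$mean * (map$significance == 1L)
  pos[pos < 0] <- 0
  tot <- colSums(pos)
  s <- sum(tot)
  if (s <= 0) {
    warning("no positive-significant responses; returning all-zero curve")
    return(stats::setNames(rep(0, length(tot)), names(tot)))
  }
  tot / s
}

#' Dispersion index of significant responses
#'
#' Per latency bin, the mean Euclidean distance of significantly
#' responsive channels from the (nearest) stimulated channel, in
#' micrometres — how far from the stimulation site the response has
#' spread at each latency. A `"pairwise"` mode instead averages distances
#' between all pairs of responsive electrodes.
#'
#' @param map A `response_map`.
#' @param geometry The session's [grid_geometry()].
#' @param stim_channels Stimulated channel ids.
#' @param mode `"from_stim"` (default) or `"pairwise"`.
#' @param signs Which significance signs count as responsive (default
#'   both positive and negative).
#' @return A `dispersion_curve` data frame: `bin` (label), `latency`
#'   (upper edge, s), `mean_distance` (um; `NA` where no channel
#'   responds), `n_responsive`.
#' @export
dispersion_index <- function(map, geometry, stim_channels,
                             mode = c("from_stim", "pairwise"),
                             signs = c(-1L, 1L)) {
  stopifnot(inherits(map, "response_map"),
            inherits(geometry, "grid_geometry"))
  mode <- match.arg(mode)
  stim_channels <- as.integer(stim_channels)
  B <- ncol(map$mean)
  md <- rep(NA_real_, B)
  nr <- integer(B)
  sp <- channel_positions(geometry, stim_channels)
  for (b in seq_len(B)) {
    resp <- map$channels[map$significance[, b] %in% signs]
    nr[b] <- length(resp)
    if (!length(resp)) next
    rp <- channel_positions(geometry, resp)
    if (mode == "from_stim") {
      dmin <- rep(Inf, length(resp))
      for (k in seq_len(nrow(sp)))
        dmin <- pmin(dmin, sqrt((rp$x - sp$x[k])^2 + (rp$y - sp$y[k])^2))
      md[b] <- mean(dmin)
    } else {
      if (length(resp) < 2L) { md[b] <- 0; next }
      md[b] <- mean(stats::dist(cbind(rp$x, rp$y)))
    }
  }
  edges <- map$latency_bins
  labs <- paste0(round(edges[-(B + 1L)] * 1000), "-",
                 round(edges[-1L] * 1000), "ms")
  structure(data.frame(bin = labs,
                       latency = map$latency_bins[-1L],
                       mean_distance = md,
                       n_responsive = nr),
            mode = mode, class = c("dispersion_curve", "data.frame"))
}

#' Detect stimulus-evoked network bursts
#'
#' Runs network-burst detection on the session's recording and reports,
#' per pulse, whether an NB started within `window` after the pulse and
#' its duration, together with the spontaneous NB duration (NBs outside
#' all post-pulse windows) for comparison.
#'
#' @param session A [stimulation_session()].
#' @param window Post-stimulus window in seconds (default 1).
#' @param ... Passed to [detect_network_bursts()].
#' @return List with `per_pulse` (data frame `pulse_time`, `evoked`,
#'   `nbd`), `n_evoked`, `evoked_nbd` (mean), `spontaneous_nbd` (mean),
#'   and the full `network_bursts` table.
#' @export
detect_evoked_nb <- function(session, window = 1, ...) {
  stopifnot(inherits(session, "stimulation_session"))
  pulses <- session$pulse_times
  if (!length(pulses))
    return(list(per_pulse = data.frame(pulse_time = numeric(0),
                                       evoked = logical(0), nbd = numeric(0)),
                n_evoked = 0L, evoked_nbd = NA_real_,
                spontaneous_nbd = NA_real_, nbs = NULL))
  nbs <- detect_network_bursts(session$spikes, ...)
  evoked <- logical(length(pulses))
  nbd <- rep(NA_real_, length(pulses))
  used <- logical(nrow(nbs))
  for (k in seq_along(pulses)) {
    hit <- which(!used & nbs$start >= pulses[k] &
                   nbs$start < pulses[k] + window)
    if (length(hit)) {
      evoked[k] <- TRUE
      nbd[k] <- nbs$end[hit[1L]] - nbs$start[hit[1L]]
      used[hit[1L]] <- TRUE
    }
  }
  spont <- nbs[!used, , drop = FALSE]
  list(per_pulse = data.frame(pulse_time = pulses, evoked = evoked, nbd = nbd),
       n_evoked = sum(evoked),
       evoked_nbd = if (any(evoked)) mean(nbd[evoked]) else NA_real_,
       spontaneous_nbd = if (nrow(spont)) mean(spont$end - spont$start)
                         else NA_real_,
       nbs = nbs)
}

#' Select the most active channels for stimulation
#'
#' Returns the `k` channels of highest mean firing rate (ties broken by
#' lower channel id), emulating the selection of the most active
#' electrodes for multi-site stimulation.
#'
#' @param set A [spike_train_set()].
#' @param k Number of channels (default 7).
#' @param min_rate Active-channel threshold in Hz.
#' @return Integer channel ids, ordered by decreasing rate.
#' @export
select_stim_channels <- function(set, k = 7L, min_rate = 0.1) {
  stopifnot(k >= 1)
  rates <- mean_firing_rate(set)
  active <- detect_active_channels(rates, min_rate)
  if (length(active) < k) {
    warning("fewer than k active channels; returning all ", length(active))
    k <- length(active)
  }
  o <- active[order(-rates[active], active)]
  o[seq_len(k)]
}
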