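#' Array-wide firing-rate time series
#'
#' Total spike count per time bin divided by the bin width, over the whole
#' array. The series covers `ceiling(duration / bin)` bins; its sum times
#' the bin width equals the total spike count (conservation).
#'
#' @param set A [spike_train_set()].
#' @param bin Bin width in seconds (default 25 ms).
#' @return An `array_rate`: data frame with columns `time` (bin centre,
#'   s), `count`, `rate` (spikes/s); bin width kept in `attr(, "bin")`.
#' @export
array_firing_rate <- function(set, bin = 0.025) {
  stopifnot(inherits(set, "spike_train_set"), bin > 0)
  nb <- ceiling(set$duration / bin)
  counts <- tabulate(pmin(floor(set$events$time / bin) + 1L, nb), nbins = nb)
  structure(data.frame(time = (seq_len(nb) - 0.5) * bin,
                       count = counts,
                       rate = counts / bin),
            bin = bin, duration = set$duration, class = c("array_rate", "data.frame"))
}

merge_intervals <- function(start, end, gap) {
  if (!length(start)) return(cbind(start = numeric(0), end = numeric(0)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- numeric(0); out_e <- numeric(0)
  for (k in seq_along(start)[-1L]) {
    if (start[k] - me < gap) {
      me <- max(me, end[k])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[k]; me <- end[k]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Network-burst detection
#'
#' A network burst (NB) is a contiguous run of time bins in which the
#' array-wide firing rate exceeds a threshold (default: mean + 3 SD of the
#' binned rate) AND at least `min_participation` of the active channels
#' fire. Runs separated by less than `merge_gap` are merged. NB rate (NBR)
#' is bursts per minute; NB duration (NBD) the mean (or median) of
#' `end - start`.
#'
#' @param set A [spike_train_set()].
#' @param bin Bin width in seconds (default 25 ms).
#' @param rate_threshold Spikes/s threshold, or `NULL` for mean + `k` SD.
#' @param k_sd SD multiplier of the automatic threshold (default 3).
#' @param min_participation Minimum fraction of active channels firing in
#'   a bin (default 0.2).
#' @param merge_gap Runs closer than this are merged (s, default 0.1).
#' @param min_rate Active-channel threshold in Hz.
#' @return A `network_bursts` object: data frame `start`, `end`,
#'   `n_channels`, `peak_rate` with the participating channel sets in
#'   `attr(, "participating")` and the recording duration in
#'   `attr(, "duration")`.
#' @export
detect_network_bursts <- function(set, bin = 0.025, rate_threshold = NULL,
                                  k_sd = 3, min_participation = 0.2,
                                  merge_gap = 0.1, min_rate = 0.1) {
  stopifnot(inherits(set, "spike_train_set"), bin > 0, merge_gap >= 0,
            min_participation >= 0, min_participation <= 1)
  empty <- structure(data.frame(start = numeric(0), end = numeric(0),
                                n_channels = integer(0),
                                peak_rate = numeric(0)),
                     participating = list(), duration = set$duration,
                     bin = bin, class = c("network_bursts", "data.frame"))
  active <- detect_active_channels(mean_firing_rate(set), min_rate)
  if (!length(active)) {
    warning("no active channels; returning no network bursts")
    return(empty)
  }
  ar <- array_firing_rate(set, bin)
  if (is.null(rate_threshold))
    rate_threshold <- mean(ar$rate) + k_sd * stats::sd(ar$rate)
  ev <- set$events
  keep <- ev$channel %in% active
  bin_idx <- pmin(floor(ev$time[keep] / bin) + 1L, nrow(ar))
  # distinct active channels firing per bin
  key <- (bin_idx - 1) * (n_channels(set$geometry) + 1) + ev$channel[keep]
  uniq <- !duplicated(key)
  particip <- tabulate(bin_idx[uniq], nbins = nrow(ar))
  need <- max(1L, ceiling(min_participation * length(active)))
  above <- ar$rate > rate_threshold & particip >= need
  if (!any(above)) return(empty)
  r <- rle(above)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  sel <- r$values
  iv <- merge_intervals((starts_idx[sel] - 1L) * bin,
                        pmin(ends_idx[sel] * bin, set$duration), merge_gap)
  part <- vector("list", nrow(iv))
  n_ch <- integer(nrow(iv))
  peak <- numeric(nrow(iv))
  for (k in seq_len(nrow(iv))) {
    in_nb <- ev$time >= iv[k, 1L] & ev$time < iv[k, 2L]
    part[[k]] <- sort(unique(ev$channel[in_nb]))
    n_ch[k] <- length(part[[k]])
    bsel <- ar$time > iv[k, 1L] & ar$time < iv[k, 2L]
    peak[k] <- if (any(bsel)) max(ar$rate[bsel]) else NA_real_
  }
  structure(data.frame(start = iv[, 1L], end = iv[, 2L],
                       n_channels = n_ch, peak_rate = peak),
            participating = part, duration = set$duration, bin = bin,
            threshold = rate_threshold,
            class = c("network_bursts", "data.frame"))
}

#' @rdname detect_network_bursts
#' @param nbs A `network_bursts` object.
#' @export
network_burst_rate <- function(nbs) {
  stopifnot(inherits(nbs, "network_bursts"))
  nrow(nbs) / (attr(nbs, "duration") / 60)
}

#' @rdname detect_network_bursts
#' @param stat Mean (default) or median NB duration.
#' @export
network_burst_duration <- function(nbs, stat = c("mean", "median")) {
  stopifnot(inherits(nbs, "network_bursts"))
  stat <- match.arg(stat)
  if (!nrow(nbs)) return(NA_real_)
  if (stat == "mean") mean(nbs$end - nbs$start) else
    stats::median(nbs$end - nbs$start)
}

#' Center-of-activity trajectory (CAT) of a network burst
#'
#' For each `cat_bin`-wide time bin within the NB, the center of activity
#' is the spike-count-weighted centroid of the firing electrodes'
#' positions: CA(t) = sum_i n_i(t) p_i / sum_i n_i(t). Bins with no spikes
#' are skipped. The first point is the NB's starting center of mass; the
#' ordered points trace its propagation.
#'
#' @param set The [spike_train_set()] the NB was detected from.
#' @param nb One row of a `network_bursts` data frame (or any list with
#'   `start` and `end` in seconds).
#' @param cat_bin Bin width in seconds (default 5 ms).
#' @return A `cat_trajectory`: data frame `t` (bin centre, s), `x`, `y`
#'   (um), `n_spikes`.
#' @export
center_of_activity_trajectory <- function(set, nb, cat_bin = 0.005) {
  stopifnot(inherits(set, "spike_train_set"), cat_bin > 0)
  start <- as.numeric(nb$start[1L]); end <- as.numeric(nb$end[1L])
  if (is.na(start) || is.na(end) || start >= end)
    stop("nb must provide start < end")
  if (start < 0 || end > set$duration)
    stop("network burst lies outside the recording")
  ev <- set$events
  sel <- ev$time >= start & ev$time < end
  ch <- ev$channel[sel]
  bin_idx <- floor((ev$time[sel] - start) / cat_bin) + 1L
  if (!length(ch))
    return(structure(data.frame(t = numeric(0), x = numeric(0),
                                y = numeric(0), n_spikes = integer(0)),
                     class = c("cat_trajectory", "data.frame")))
  pos <- channel_positions(set$geometry, ch)
  sx <- rowsum(pos$x, bin_idx)
  sy <- rowsum(pos$y, bin_idx)
  nn <- tabulate(bin_idx)
  bins <- as.integer(rownames(sx))
  nb_counts <- nn[bins]
  structure(data.frame(t = start + (bins - 0.5) * cat_bin,
                       x = sx[, 1L] / nb_counts,
                       y = sy[, 1L] / nb_counts,
                       n_spikes = nb_counts),
            class = c("cat_trajectory", "data.frame"))
}
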