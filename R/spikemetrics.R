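#' Per-channel mean firing rate
#'
#' Spike count divided by recording duration for every channel of the
#' geometry; silent channels get 0 Hz.
#'
#' @param set A [spike_train_set()].
#' @return Named numeric vector of rates in Hz, one entry per channel
#'   (names are channel ids).
#' @export
mean_firing_rate <- function(set) {
  stopifnot(inherits(set, "spike_train_set"), set$duration > 0)
  n <- n_channels(set$geometry)
  counts <- tabulate(set$events$channel, nbins = n)
  stats::setNames(counts / set$duration, seq_len(n))
}

#' Active-channel detection
#'
#' A channel is active when its mean firing rate reaches `min_rate`
#' (default 0.1 Hz, i.e. 30 spikes in a 5-minute recording).
#'
#' @param rates Per-channel rates from [mean_firing_rate()].
#' @param min_rate Threshold in Hz.
#' @return Integer vector of active channel ids.
#' @export
detect_active_channels <- function(rates, min_rate = 0.1) {
  stopifnot(min_rate >= 0)
  # at min_rate 0 the rule still excludes silent channels
  as.integer(which(rates >= min_rate & rates > 0))
}

#' Single-channel burst detection (fixed ISI threshold)
#'
#' A burst is a maximal run of consecutive spikes on one channel in which
#' every inter-spike interval is at most `max_isi`, containing at least
#' `min_spikes` spikes. The fixed-threshold rule (100 ms, 5 spikes by
#' default) is the standard simple parameterization for MEA cultures;
#' both parameters are exposed.
#'
#' @param set A [spike_train_set()].
#' @param max_isi Maximum inter-spike interval within a burst (s).
#' @param min_spikes Minimum spikes per burst (>= 2).
#' @return Data frame `channel`, `start`, `end`, `n_spikes`, one row per
#'   burst, ordered by channel then start time.
#' @export
detect_bursts <- function(set, max_isi = 0.1, min_spikes = 5L) {
  stopifnot(inherits(set, "spike_train_set"), max_isi > 0, min_spikes >= 2)
  ev <- set$events
  if (!nrow(ev))
    return(data.frame(channel = integer(0), start = numeric(0),
                      end = numeric(0), n_spikes = integer(0)))
  o <- order(ev$channel, ev$time)
  ch <- ev$channel[o]
  tm <- ev$time[o]
  # run starts: first spike of a channel, or ISI > max_isi
  new_run <- c(TRUE, ch[-1L] != ch[-length(ch)] |
                 (tm[-1L] - tm[-length(tm)]) > max_isi)
  run_id <- cumsum(new_run)
  len <- tabulate(run_id)
  keep <- which(len >= min_spikes)
  if (!length(keep))
    return(data.frame(channel = integer(0), start = numeric(0),
                      end = numeric(0), n_spikes = integer(0)))
  first <- which(new_run)
  res <- data.frame(channel = ch[first[keep]],
                    start = tm[first[keep]],
                    end = tm[first[keep] + len[keep] - 1L],
                    n_spikes = len[keep])
  res[order(res$channel, res$start), , drop = FALSE]
}

#' Per-channel activity summary and array aggregates
#'
#' Combines firing rates, burst annotations and the active-channel rule
#' into the per-channel metric set: mean firing rate (MFR), mean burst
#' rate (MBR, bursts/min), mean burst duration (MBD, s), and the fraction
#' of "random" spikes (spikes outside any detected burst). Array-level
#' aggregates: percentage of bursting electrodes (channels with at least
#' one burst, among active channels by default) and the mean random-spike
#' percentage over active channels.
#'
#' @param set A [spike_train_set()].
#' @param bursts Burst table from [detect_bursts()] on the same set;
#'   computed with defaults if `NULL`.
#' @param min_rate Active-channel threshold (Hz).
#' @param denominator `"active"` (default) or `"all"`: denominator of the
#'   bursting-electrode percentage.
#' @return A `channel_summary`: list with `channels` (data frame
#'   `channel`, `mfr`, `is_active`, `n_bursts`, `mbr`, `mbd`,
#'   `random_spike_fraction`, `is_bursting`) and `aggregates` (list
#'   `n_active`, `pct_bursting_electrodes`, `mbr`, `mbd`,
#'   `pct_random_spikes`).
#' @export
summarize_channels <- function(set, bursts = NULL, min_rate = 0.1,
                               denominator = c("active", "all")) {
  stopifnot(inherits(set, "spike_train_set"))
  denominator <- match.arg(denominator)
  if (is.null(bursts)) bursts <- detect_bursts(set)
  n <- n_channels(set$geometry)
  if (nrow(bursts) && any(bursts$channel < 1L | bursts$channel > n))
    stop("burst references a channel absent from the set's geometry")
  rates <- mean_firing_rate(set)
  total <- tabulate(set$events$channel, nbins = n)
  n_bursts <- tabulate(bursts$channel, nbins = n)
  burst_spikes <- integer(n)
  burst_dur <- numeric(n)
  if (nrow(bursts)) {
    agg <- rowsum(cbind(bursts$n_spikes, bursts$end - bursts$start),
                  bursts$channel)
    idx <- as.integer(rownames(agg))
    burst_spikes[idx] <- agg[, 1L]
    burst_dur[idx] <- agg[, 2L]
  }
  if (any(burst_spikes > total))
    stop("burst spike counts exceed channel totals; bursts do not match set")
  active <- detect_active_channels(rates, min_rate)
  is_active <- seq_len(n) %in% active
  rsf <- ifelse(total > 0, (total - burst_spikes) / total, NA_real_)
  channels <- data.frame(
    channel = seq_len(n),
    mfr = as.numeric(rates),
    is_active = is_active,
    n_bursts = n_bursts,
    mbr = n_bursts / (set$duration / 60),
    mbd = ifelse(n_bursts > 0, burst_dur / n_bursts, NA_real_),
    random_spike_fraction = rsf,
    is_bursting = n_bursts > 0)
  denom <- if (denominator == "active") length(active) else n
  bursting <- channels$is_bursting & (denominator == "all" | is_active)
  aggregates <- list(
    n_active = length(active),
    pct_bursting_electrodes =
      if (denom > 0) 100 * sum(bursting) / denom else NA_real_,
    mbr = mean(channels$mbr[is_active]),
    mbd = mean(channels$mbd[is_active & channels$is_bursting]),
    pct_random_spikes =
      100 * mean(rsf[is_active], na.rm = TRUE))
  structure(list(channels = channels, aggregates = aggregates,
                 params = list(min_rate = min_rate,
                               denominator = denominator)),
            class = "channel_summary")
}

#' @export
print.channel_summary <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf(paste0("<channel_summary> %d active channels, %.1f%% bursting",
                     " electrodes,\n  MBR %.3g bursts/min, MBD %.3g s,",
                     " %.1f%% random spikes\n"),
              a$n_active, a$pct_bursting_electrodes, a$mbr, a$mbd,
              a$pct_random_spikes))
  invisible(x)
}
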