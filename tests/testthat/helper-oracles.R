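# Independent brute-force oracles used to check the package's
# implementations on small fixtures. These deliberately use naive
# quadratic scans, not the vectorized code paths under test.

small_grid <- function(n = 8L, pitch = 60) grid_geometry(n, n, pitch)

# maximal runs of same-channel spikes with every ISI <= max_isi
oracle_bursts <- function(set, max_isi = 0.1, min_spikes = 5L) {
  out <- list()
  for (ch in sort(unique(set$events$channel))) {
    tt <- sort(set$events$time[set$events$channel == ch])
    i <- 1L
    while (i <= length(tt)) {
      j <- i
      while (j < length(tt) && tt[j + 1L] - tt[j] <= max_isi) j <- j + 1L
      if (j - i + 1L >= min_spikes)
        out[[length(out) + 1L]] <- data.frame(
          channel = ch, start = tt[i], end = tt[j], n_spikes = j - i + 1L)
      i <- j + 1L
    }
  }
  if (!length(out))
    return(data.frame(channel = integer(0), start = numeric(0),
                      end = numeric(0), n_spikes = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# explicit scan of the binned count matrix
oracle_network_bursts <- function(set, bin = 0.025, rate_threshold = NULL,
                                  k_sd = 3, min_participation = 0.2,
                                  merge_gap = 0.1, min_rate = 0.1) {
  nbins <- ceiling(set$duration / bin)
  n <- n_channels(set$geometry)
  counts <- matrix(0L, nbins, n)
  for (r in seq_len(nrow(set$events))) {
    b <- min(floor(set$events$time[r] / bin) + 1L, nbins)
    counts[b, set$events$channel[r]] <- counts[b, set$events$channel[r]] + 1L
  }
  rates <- colSums(counts) / set$duration
  active <- which(rates >= min_rate & rates > 0)
  arr <- rowSums(counts) / bin
  if (is.null(rate_threshold))
    rate_threshold <- mean(arr) + k_sd * stats::sd(arr)
  need <- max(1L, ceiling(min_participation * length(active)))
  above <- logical(nbins)
  for (b in seq_len(nbins))
    above[b] <- arr[b] > rate_threshold &&
      sum(counts[b, active] > 0) >= need
  ivs <- list()
  b <- 1L
  while (b <= nbins) {
    if (above[b]) {
      e <- b
      while (e < nbins && above[e + 1L]) e <- e + 1L
      ivs[[length(ivs) + 1L]] <- c((b - 1L) * bin, min(e * bin, set$duration))
      b <- e + 1L
    } else b <- b + 1L
  }
  if (!length(ivs)) return(data.frame(start = numeric(0), end = numeric(0)))
  merged <- list(ivs[[1L]])
  for (k in seq_along(ivs)[-1L]) {
    last <- merged[[length(merged)]]
    if (ivs[[k]][1L] - last[2L] < merge_gap)
      merged[[length(merged)]] <- c(last[1L], max(last[2L], ivs[[k]][2L]))
    else merged[[length(merged) + 1L]] <- ivs[[k]]
  }
  data.frame(start = vapply(merged, `[`, numeric(1), 1L),
             end = vapply(merged, `[`, numeric(1), 2L))
}

# enumerate all pairs above threshold
oracle_graph_links <- function(values, channels, threshold) {
  out <- list()
  C <- length(channels)
  for (i in seq_len(C - 1L))
    for (j in (i + 1L):C)
      if (values[i, j] >= threshold)
        out[[length(out) + 1L]] <- c(channels[i], channels[j])
  if (!length(out)) return(data.frame(a = integer(0), b = integer(0)))
  m <- do.call(rbind, out)
  data.frame(a = m[, 1L], b = m[, 2L])
}

# mean distance of responsive channels from the nearest stim channel
oracle_dispersion <- function(resp_channels, geometry, stim_channels) {
  if (!length(resp_channels)) return(NA_real_)
  d <- numeric(length(resp_channels))
  for (k in seq_along(resp_channels)) {
    dd <- Inf
    for (s in stim_channels)
      dd <- min(dd, channel_distance(geometry, resp_channels[k], s))
    d[k] <- dd
  }
  mean(d)
}

# hand-build a response_map for the operations downstream of
# evoked_response (significance pattern is the only input they use)
fake_response_map <- function(channels, edges, mean_mat, sig_mat) {
  structure(list(channels = as.integer(channels), latency_bins = edges,
                 mean = mean_mat, ci_lower = mean_mat, ci_upper = mean_mat,
                 significance = sig_mat, n_pulses = 25L,
                 params = list(alpha = 0.05)),
            class = "response_map")
}

# reference integration of a single two-variable neuron under constant
# drive, forward Euler at a fine step; returns spike times in ms
oracle_izhi_single <- function(I, total_ms, dt = 0.01,
                               a = 0.02, b = 0.2, cc = -65, d = 8) {
  v <- -65; u <- b * v
  spikes <- numeric(0)
  t <- 0
  while (t < total_ms) {
    v <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I)
    u <- u + dt * a * (b * v - u)
    if (v >= 30) {
      spikes <- c(spikes, t)
      v <- cc; u <- u + d
    }
    t <- t + dt
  }
  spikes
}
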