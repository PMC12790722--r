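## Synthetic HD-MEA recordings with planted ground truth.
## Everything here is a statistical fixture, not a biophysical model: the
## generators reproduce the statistical structure the downstream analyses
## assume (Poisson background, propagating network bursts, pairwise
## correlations, distance/latency stimulus responses) so that every
## pipeline stage can be tested against known truth.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Expected inhibitory fraction of a culture mixture
#'
#' Cultures are mixed from components with known inhibitory-interneuron
#' percentages (e.g. a dorsal-telencephalic culture with 7% PV+/SST+ cells
#' and a ventral-telencephalic one with 80%). The expected inhibitory
#' percentage of a mixture is the mixing-weighted mean of the component
#' percentages: an 80:20 mix of 7% and 80% components carries
#' 0.8 * 7 + 0.2 * 80 = 21.6% inhibitory neurons.
#'
#' @param weights Non-negative mixing weights summing to 1.
#' @param inhibitory_pct Percent inhibitory neurons per component, in
#'   `[0, 100]`; same length as `weights`.
#' @return The expected inhibitory percentage of the mixture.
#' @examples
#' expected_inhibitory_fraction(c(0.8, 0.2), c(7, 80))  # 21.6
#' expected_inhibitory_fraction(c(0.5, 0.5), c(7, 80))  # 43.5
#' @export
expected_inhibitory_fraction <- function(weights, inhibitory_pct) {
  stopifnot(is.numeric(weights), is.numeric(inhibitory_pct),
            length(weights) == length(inhibitory_pct), length(weights) >= 1L)
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (any(inhibitory_pct < 0 | inhibitory_pct > 100))
    stop("inhibitory_pct must lie in [0, 100]")
  sum(weights * inhibitory_pct)
}

#' Log-normal per-channel firing-rate map
#'
#' Draws one background rate per channel from a log-normal distribution
#' (default median 0.5 Hz), optionally silencing a fraction of channels,
#' so that active/inactive channel detection is exercised downstream.
#'
#' @param geometry A [grid_geometry()].
#' @param median Median rate in Hz of the firing channels.
#' @param sdlog Log-scale standard deviation.
#' @param silent_fraction Fraction of channels set to 0 Hz.
#' @param seed Integer seed; same seed gives the same map.
#' @return Numeric vector of rates (Hz), one per channel.
#' @export
lognormal_rate_map <- function(geometry, median = 0.5, sdlog = 0.8,
                               silent_fraction = 0, seed = NULL) {
  n <- n_channels(geometry)
  stopifnot(median >= 0, sdlog >= 0,
            silent_fraction >= 0, silent_fraction <= 1)
  with_seed(seed, {
    r <- stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
    if (silent_fraction > 0) {
      k <- round(silent_fraction * n)
      if (k > 0) r[sample.int(n, k)] <- 0
    }
    r
  })
}

#' Generate Poisson background activity
#'
#' Independent homogeneous Poisson spike trains per channel — the
#' uncorrelated "random spikes" regime. Deterministic given
#' `(rate_map, duration, seed)`.
#'
#' @param geometry A [grid_geometry()].
#' @param duration Recording length in seconds (default 300, i.e. the 5-min
#'   integration window used for activity maps).
#' @param rate_map Per-channel rates in Hz (scalar recycled, or one value
#'   per channel). Default: [lognormal_rate_map()] drawn with `seed`.
#' @param seed Integer seed.
#' @param label Condition tag.
#' @return A [spike_train_set()].
#' @export
generate_background <- function(geometry, duration = 300, rate_map = NULL,
                                seed = NULL, label = "") {
  stopifnot(duration > 0)
  n <- n_channels(geometry)
  with_seed(seed, {
    if (is.null(rate_map))
      rate_map <- stats::rlnorm(n, meanlog = log(0.5), sdlog = 0.8)
    if (length(rate_map) == 1L) rate_map <- rep(rate_map, n)
    stopifnot(length(rate_map) == n)
    if (any(rate_map < 0)) stop("rates must be non-negative")
    counts <- stats::rpois(n, rate_map * duration)
    ch <- rep.int(seq_len(n), counts)
    tm <- stats::runif(sum(counts), 0, duration)
    spike_train_set(ch, tm, duration, geometry, label)
  })
}

## Evenly spaced planted times with bounded jitter: guarantees the
## separation invariant that downstream merge rules assume.
planted_times <- function(n, duration, margin, jitter_frac = 0.2) {
  if (n <= 0) return(numeric(0))
  usable <- duration - 2 * margin
  spacing <- usable / n
  centers <- margin + (seq_len(n) - 0.5) * spacing
  centers + stats::runif(n, -jitter_frac * spacing, jitter_frac * spacing)
}

#' Superimpose propagating network bursts on a background recording
#'
#' Plants `nb_rate` network bursts (NBs) per minute at well-separated
#' times. Each NB recruits a random `participation` fraction of channels;
#' a channel's burst onset lags the NB start by its distance from a
#' randomly drawn origin divided by `propagation_speed`, producing a
#' radially propagating wave and hence a non-trivial center-of-activity
#' trajectory. During its onset window each recruited channel fires as a
#' Poisson process at `burst_rate` Hz.
#'
#' @param base Background [spike_train_set()].
#' @param nb_rate Planted NBs per minute (0 = return `base` unchanged).
#' @param nb_duration Per-channel burst duration in seconds.
#' @param participation Fraction of channels recruited per NB, in (0, 1].
#' @param propagation_speed Wavefront speed in um/ms (`Inf` = simultaneous
#'   onsets).
#' @param burst_rate Within-burst firing rate in Hz per recruited channel.
#' @param origin_margin Keep NB origins at least this far (um) from the
#'   grid boundary (default 0 = anywhere). Useful when planted origins
#'   must be identifiable from the early center of activity, which is
#'   biased inward for origins whose activity disk is clipped by the
#'   array edge.
#' @param seed Integer seed.
#' @return List with `spikes` (merged [spike_train_set()]) and `truth`, a
#'   `synthetic_ground_truth` list with `nb_times`, `nb_origin` (data
#'   frame `channel`, `x`, `y`), and the generator parameters.
#' @export
generate_network_bursts <- function(base, nb_rate = 2, nb_duration = 0.3,
                                    participation = 0.6,
                                    propagation_speed = 100,
                                    burst_rate = 100, origin_margin = 0,
                                    seed = NULL) {
  stopifnot(inherits(base, "spike_train_set"),
            nb_rate >= 0, nb_duration > 0, propagation_speed > 0)
  if (participation <= 0 || participation > 1)
    stop("participation must lie in (0, 1]")
  g <- base$geometry
  n <- n_channels(g)
  n_nb <- round(nb_rate * base$duration / 60)
  truth <- structure(list(nb_times = numeric(0),
                          nb_origin = data.frame(channel = integer(0),
                                                 x = numeric(0), y = numeric(0)),
                          params = list(nb_rate = nb_rate,
                                        nb_duration = nb_duration,
                                        participation = participation,
                                        propagation_speed = propagation_speed,
                                        burst_rate = burst_rate)),
                     class = "synthetic_ground_truth")
  if (n_nb == 0) return(list(spikes = base, truth = truth))
  pos <- channel_positions(g)
  # widest possible onset spread, to keep events inside the recording
  max_lag_s <- if (is.finite(propagation_speed))
    max(channel_distance(g, 1L, n:1L)) / propagation_speed / 1000 else 0
  origin_pool <- which(pos$x >= origin_margin & pos$y >= origin_margin &
                         pos$x <= max(pos$x) - origin_margin &
                         pos$y <= max(pos$y) - origin_margin)
  if (!length(origin_pool)) stop("origin_margin excludes every channel")
  with_seed(seed, {
    starts <- planted_times(n_nb, base$duration,
                            margin = nb_duration + max_lag_s + 0.5)
    origins <- origin_pool[sample.int(length(origin_pool), n_nb,
                                      replace = TRUE)]
    n_part <- max(1L, round(participation * n))
    ch_all <- vector("list", n_nb)
    tm_all <- vector("list", n_nb)
    for (k in seq_len(n_nb)) {
      part <- sample.int(n, n_part)
      lag_s <- if (is.finite(propagation_speed))
        channel_distance(g, origins[k], part) / propagation_speed / 1000
      else rep(0, n_part)
      counts <- stats::rpois(n_part, burst_rate * nb_duration)
      ch_all[[k]] <- rep.int(part, counts)
      onset <- rep.int(starts[k] + lag_s, counts)
      tm_all[[k]] <- onset + stats::runif(sum(counts), 0, nb_duration)
    }
    ch <- unlist(ch_all)
    tm <- unlist(tm_all)
    keep <- tm >= 0 & tm < base$duration
    burst_set <- spike_train_set(ch[keep], tm[keep], base$duration, g)
    truth$nb_times <- starts
    truth$nb_origin <- pos[origins, , drop = FALSE]
    rownames(truth$nb_origin) <- NULL
    list(spikes = merge_spike_trains(base, burst_set, label = base$label),
         truth = truth)
  })
}

#' Copy-with-jitter planted pairwise correlations
#'
#' For each planted `(source, target)` pair, each source spike is copied
#' to the target channel with probability `copy_prob` and Gaussian timing
#' jitter, creating correlation detectable by [pairwise_correlation()].
#'
#' @param base Background [spike_train_set()].
#' @param pairs Two-column integer matrix (or data frame) of
#'   `(source, target)` channel pairs; no self-pairs.
#' @param jitter Jitter SD in seconds.
#' @param copy_prob Copy probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return List with `spikes` and `truth` (element `pairs`: the planted
#'   pairs as an unordered-pair data frame).
#' @export
plant_correlations <- function(base, pairs, jitter = 0.002, copy_prob = 0.7,
                               seed = NULL) {
  stopifnot(inherits(base, "spike_train_set"), jitter >= 0,
            copy_prob >= 0, copy_prob <= 1)
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L)
  storage.mode(pairs) <- "integer"
  n <- n_channels(base$geometry)
  if (any(pairs < 1L | pairs > n)) stop("pair references unknown channel")
  if (any(pairs[, 1L] == pairs[, 2L])) stop("self-pairs are not allowed")
  ev <- base$events
  with_seed(seed, {
    ch_new <- vector("list", nrow(pairs))
    tm_new <- vector("list", nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      src_t <- ev$time[ev$channel == pairs[k, 1L]]
      keep <- stats::runif(length(src_t)) < copy_prob
      t2 <- src_t[keep] + stats::rnorm(sum(keep), 0, jitter)
      t2 <- t2[t2 >= 0 & t2 < base$duration]
      ch_new[[k]] <- rep.int(pairs[k, 2L], length(t2))
      tm_new[[k]] <- t2
    }
    extra <- spike_train_set(unlist(ch_new), unlist(tm_new),
                             base$duration, base$geometry)
    truth <- structure(list(pairs = data.frame(
      a = pmin(pairs[, 1L], pairs[, 2L]),
      b = pmax(pairs[, 1L], pairs[, 2L]))),
      class = "synthetic_ground_truth")
    list(spikes = merge_spike_trains(base, extra, label = base$label),
         truth = truth)
  })
}

#' Distance/latency response kernel constructor
#'
#' Builds a kernel function `f(distance_um, latency_s)` returning the
#' stimulus-evoked rate change in Hz: a Gaussian latency profile whose
#' amplitude decays with distance from the stimulation site. Negative
#' `amplitude` gives a suppressive kernel.
#'
#' @param amplitude Peak rate change in Hz at distance 0.
#' @param latency_peak,latency_sd Latency profile centre/width in seconds.
#' @param distance_scale Exponential decay length in micrometres
#'   (`Inf` = no spatial decay).
#' @param max_distance Hard cutoff: zero response beyond this distance (um).
#' @return A function of `(distance_um, latency_s)`.
#' @export
make_response_kernel <- function(amplitude = 200, latency_peak = 0.01,
                                 latency_sd = 0.003, distance_scale = 300,
                                 max_distance = Inf) {
  force(amplitude); force(latency_peak); force(latency_sd)
  force(distance_scale); force(max_distance)
  function(distance_um, latency_s) {
    amp <- amplitude * exp(-(latency_s - latency_peak)^2 / (2 * latency_sd^2))
    spatial <- if (is.finite(distance_scale))
      exp(-distance_um / distance_scale) else 1
    out <- amp * spatial
    out[distance_um > max_distance] <- 0
    out
  }
}

#' Generate a synthetic stimulation session
#'
#' Baseline Poisson firing plus, after each pulse, extra spikes whose
#' per-channel expected count follows the planted kernel's
#' distance/latency profile (distance to the nearest stimulated channel).
#' Suppressive (negative) kernel values thin the baseline in the response
#' window, clipped so the net rate never drops below zero.
#'
#' @param geometry A [grid_geometry()].
#' @param stim_channels Stimulated channel ids.
#' @param n_pulses Number of pulses (default 25).
#' @param kernel `NULL` (no planted response) or a function
#'   `f(distance_um, latency_s)` in Hz, e.g. from [make_response_kernel()].
#' @param baseline_rate Baseline rate in Hz (scalar or per channel).
#' @param pulse_interval Pulse spacing in seconds (must exceed twice the
#'   150 ms analysis window).
#' @param window Response window length in seconds after each pulse.
#' @param seed Integer seed.
#' @return List with `session` (a [stimulation_session()]) and `truth`
#'   (kernel and parameters).
#' @export
generate_stim_session <- function(geometry, stim_channels, n_pulses = 25,
                                  kernel = NULL, baseline_rate = 1,
                                  pulse_interval = 1, window = 0.15,
                                  seed = NULL) {
  stopifnot(n_pulses >= 1, pulse_interval > 2 * window)
  n <- n_channels(geometry)
  stim_channels <- as.integer(stim_channels)
  if (any(stim_channels < 1L | stim_channels > n))
    stop("stim channel outside geometry")
  duration <- n_pulses * pulse_interval + 1
  pulse_times <- 0.5 + (seq_len(n_pulses) - 1) * pulse_interval
  if (length(baseline_rate) == 1L) baseline_rate <- rep(baseline_rate, n)
  stopifnot(length(baseline_rate) == n)
  # distance of every channel to its nearest stimulated channel
  pos <- channel_positions(geometry)
  sp <- channel_positions(geometry, stim_channels)
  dmin <- rep(Inf, n)
  for (k in seq_along(stim_channels))
    dmin <- pmin(dmin, sqrt((pos$x - sp$x[k])^2 + (pos$y - sp$y[k])^2))
  with_seed(seed, {
    base <- generate_background(geometry, duration, baseline_rate)
    ch <- base$events$channel
    tm <- base$events$time
    if (!is.null(kernel)) {
      # evaluate the kernel on a 1 ms latency grid over the window
      lat <- seq(0.0005, window - 0.0005, by = 0.001)
      K <- outer(dmin, lat, kernel)           # n x length(lat), Hz
      Kpos <- pmax(K, 0)
      Kneg <- pmax(-K, 0)
      exp_extra <- Kpos * 0.001               # expected extra spikes per cell
      for (p in pulse_times) {
        n_extra <- stats::rpois(length(exp_extra), exp_extra)
        idx <- which(n_extra > 0)
        if (length(idx)) {
          chx <- rep.int((idx - 1L) %% n + 1L, n_extra[idx])
          latx <- lat[(idx - 1L) %/% n + 1L]
          tmx <- p + rep.int(latx, n_extra[idx]) +
            stats::runif(sum(n_extra[idx]), -0.0005, 0.0005)
          ch <- c(ch, chx)
          tm <- c(tm, tmx)
        }
        # suppression: thin baseline spikes in the window
        if (any(Kneg > 0)) {
          in_win <- which(tm >= p & tm < p + window)
          if (length(in_win)) {
            li <- pmin(length(lat), pmax(1L, ceiling((tm[in_win] - p) / 0.001)))
            supp <- Kneg[cbind(ch[in_win], li)]
            p_del <- pmin(1, supp / pmax(baseline_rate[ch[in_win]], 1e-12))
            drop <- in_win[stats::runif(length(in_win)) < p_del]
            if (length(drop)) { ch <- ch[-drop]; tm <- tm[-drop] }
          }
        }
      }
    }
    spikes <- spike_train_set(ch, tm, duration, geometry)
    truth <- structure(list(kernel = kernel, stim_channels = stim_channels,
                            params = list(n_pulses = n_pulses,
                                          baseline_rate = baseline_rate,
                                          window = window)),
                       class = "synthetic_ground_truth")
    list(session = stimulation_session(spikes, pulse_times, stim_channels,
                                       window = window),
         truth = truth)
  })
}

#' Network-burst rate implied by an E/I mixture (fixture contract)
#'
#' Maps the excitatory fraction of a culture to the planted network-burst
#' rate of the synthetic generator. The mapping is a Gaussian bump peaking
#' at intermediate excitatory fractions, so that mixed cultures burst more
#' than either pure extreme. This encodes the qualitative shape the
#' generator is contracted to produce for testing; it is a fixture
#' contract, not a biological claim.
#'
#' @param excitatory_fraction Fraction of excitatory-like drive in `[0, 1]`.
#' @param max_rate Peak NB rate in bursts/min.
#' @param center,width Location and width of the bump.
#' @return NB rate in bursts/min.
#' @export
ei_nb_rate <- function(excitatory_fraction, max_rate = 3,
                       center = 0.65, width = 0.18) {
  stopifnot(all(excitatory_fraction >= 0 & excitatory_fraction <= 1))
  max_rate * exp(-(excitatory_fraction - center)^2 / (2 * width^2))
}

#' One-call synthetic recording for an E/I scenario
#'
#' Background plus planted network bursts at the rate implied by
#' [ei_nb_rate()] for the given excitatory fraction.
#'
#' @param geometry A [grid_geometry()].
#' @param excitatory_fraction Excitatory fraction in `[0, 1]`.
#' @param duration Seconds.
#' @param seed Integer seed.
#' @param label Condition tag.
#' @param ... Passed to [generate_network_bursts()].
#' @return List with `spikes` and `truth` as in [generate_network_bursts()].
#' @export
generate_recording <- function(geometry, excitatory_fraction, duration = 300,
                               seed = NULL, label = "", ...) {
  base <- generate_background(geometry, duration, seed = seed, label = label)
  seed2 <- if (is.null(seed)) NULL else as.integer(seed) + 104729L
  generate_network_bursts(base, nb_rate = ei_nb_rate(excitatory_fraction),
                          seed = seed2, ...)
}
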