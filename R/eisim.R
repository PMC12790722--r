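#' Simulation configuration for the E/I spiking network
#'
#' Parameters of a self-organizing network of two-variable (Izhikevich)
#' quadratic integrate-and-fire neurons: regular-spiking excitatory cells
#' (a = 0.02, d = 8) and fast-spiking inhibitory cells (a = 0.1, d = 2),
#' sparse random wiring with conduction delays, additive spike-timing-
#' dependent plasticity (STDP) on excitatory synapses, and a weak random
#' external drive (one randomly chosen neuron receives a current kick per
#' millisecond). All values are config-exposed.
#'
#' @param n_neurons Network size (default 1000).
#' @param n_excitatory Number of excitatory neurons (rest inhibitory).
#' @param synapses_per_neuron Outgoing synapses per neuron (default 100).
#' @param delay_range_exc Integer ms range of excitatory conduction
#'   delays (default 1-20).
#' @param delay_inh Inhibitory delay in ms (default 1).
#' @param init_weight_exc,init_weight_inh Initial synaptic weights
#'   (default +6 / -5).
#' @param weight_cap Maximum excitatory weight (default 10).
#' @param stdp List `A_plus`, `A_minus`, `tau_ms` (defaults 0.1, 0.12, 20).
#' @param stdp_enabled Apply STDP to excitatory weights (default TRUE).
#' @param input_current External drive amplitude (default 20).
#' @param bias_current Optional constant per-neuron drive vector (length
#'   `n_neurons`), mainly for single-neuron validation runs.
#' @param dt Integration step in ms (default 1; two half-steps of the
#'   membrane equation per step).
#' @param duration Scored simulation length in seconds (default 120).
#' @param warmup STDP warm-up excluded from the returned raster (s,
#'   default 60).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_neurons = 1000L, n_excitatory = 800L,
                       synapses_per_neuron = 100L,
                       delay_range_exc = c(1L, 20L), delay_inh = 1L,
                       init_weight_exc = 6, init_weight_inh = -5,
                       weight_cap = 10,
                       stdp = list(A_plus = 0.1, A_minus = 0.12, tau_ms = 20),
                       stdp_enabled = TRUE, input_current = 20,
                       bias_current = NULL,
                       dt = 1, duration = 120, warmup = 60, seed = 1L) {
  cfg <- list(n_neurons = as.integer(n_neurons),
              n_excitatory = as.integer(n_excitatory),
              synapses_per_neuron = as.integer(synapses_per_neuron),
              delay_range_exc = as.integer(delay_range_exc),
              delay_inh = as.integer(delay_inh),
              init_weight_exc = init_weight_exc,
              init_weight_inh = init_weight_inh,
              weight_cap = weight_cap, stdp = stdp,
              stdp_enabled = isTRUE(stdp_enabled),
              input_current = input_current,
              bias_current = as.numeric(bias_current), dt = dt,
              duration = duration, warmup = warmup,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_neurons >= 1, n_excitatory >= 0, n_excitatory <= n_neurons,
              dt > 0, 1 / dt == round(1 / dt), duration > 0, warmup >= 0,
              weight_cap > 0, synapses_per_neuron >= 1,
              length(delay_range_exc) == 2, delay_range_exc[1] >= 1)
  })
  structure(cfg, class = "sim_config")
}

#' Build the random synaptic network
#'
#' The first `n_excitatory` neurons are excitatory, the rest inhibitory.
#' Every neuron gets `synapses_per_neuron` random outgoing targets
#' without self-connections; inhibitory neurons target excitatory neurons
#' only (when enough exist). Excitatory delays are uniform on the
#' configured integer ms range; inhibitory delays are fixed. The wiring
#' is deterministic per seed.
#'
#' @param config A [sim_config()].
#' @return A `sim_network`: list with `targets`, `delays`, `weights`
#'   (n_neurons x synapses_per_neuron matrices) and the config.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$n_neurons
  M <- config$synapses_per_neuron
  ne <- config$n_excitatory
  if (M >= N) stop("synapses_per_neuron must be smaller than n_neurons")
  with_seed(config$seed, {
    targets <- matrix(0L, N, M)
    for (i in seq_len(N)) {
      pool <- if (i > ne && ne >= M) seq_len(ne) else setdiff(seq_len(N), i)
      targets[i, ] <- sample(pool, M)
    }
    delays <- matrix(config$delay_inh, N, M)
    if (ne > 0)
      delays[seq_len(ne), ] <- sample(
        seq(config$delay_range_exc[1L], config$delay_range_exc[2L]),
        ne * M, replace = TRUE)
    weights <- matrix(config$init_weight_inh, N, M)
    if (ne > 0) weights[seq_len(ne), ] <- config$init_weight_exc
    structure(list(targets = targets, delays = delays, weights = weights,
                   config = config),
              class = "sim_network")
  })
}

#' Run the spiking-network simulation
#'
#' Integrates the two-variable membrane equations at step `dt` (two
#' half-steps per step) with spike-reset, delayed synaptic delivery,
#' one-random-neuron-per-ms external drive, and (when enabled) additive
#' STDP on excitatory weights with per-second consolidation, clipped to
#' `[0, weight_cap]`. The warm-up period is excluded from the returned
#' raster; spike times are reported in ms from the end of warm-up.
#'
#' @param network A [build_network()] result.
#' @param config Optional [sim_config()] override (default: the network's).
#' @param record_raster Keep the full spike raster (default TRUE). With
#'   FALSE only the per-ms population counts are kept, which is what the
#'   INF metric needs and far smaller for high-firing regimes.
#' @return A `sim_result`: list with `raster` (data frame `neuron`,
#'   `time_ms`), `pop_counts` (per-ms population spike counts of the
#'   scored window), `final_weights`, `config`.
#' @export
simulate_network <- function(network, config = network$config,
                             record_raster = TRUE) {
  stopifnot(inherits(network, "sim_network"), inherits(config, "sim_config"))
  total_ms <- (config$warmup + config$duration) * 1000
  res <- with_seed(config$seed + 1L, {
    .izhi_simulate(config$n_neurons, config$n_excitatory,
                   network$targets, network$delays, network$weights,
                   config$dt, total_ms, config$warmup * 1000,
                   config$input_current, config$stdp_enabled,
                   config$stdp$A_plus, config$stdp$A_minus,
                   config$stdp$tau_ms, config$weight_cap,
                   weight_drift = 0.01, sd_damping = 0.9,
                   bias_current = config$bias_current,
                   record_raster = record_raster)
  })
  structure(list(raster = data.frame(neuron = res$neuron,
                                     time_ms = res$time_ms),
                 pop_counts = res$pop_counts,
                 final_weights = res$weights, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d spikes, %d neurons (%d exc), %g s scored\n",
              nrow(x$raster), x$config$n_neurons, x$config$n_excitatory,
              x$config$duration))
  invisible(x)
}

#' Instantaneous network firing (INF)
#'
#' Population spike counts per bin (default 10 ms); an INF event is a
#' maximal run of bins whose count exceeds a threshold fraction `phi` of
#' the network size, each contributing one event at its peak. The INF
#' rate (events/min) is the simulated analogue of the biological
#' network-burst rate.
#'
#' @param result A `sim_result` (or any list with a `raster` data frame
#'   and `config`).
#' @param bin Bin width in ms (default 10).
#' @param phi Threshold fraction of `n_neurons` (default 0.25).
#' @return An `inf_series`: list with `bin`, `counts`, `events` (data
#'   frame `time_ms`, `peak_count`), `inf_rate` (events/min),
#'   `duration_s`.
#' @export
instantaneous_network_firing <- function(result, bin = 10, phi = 0.25) {
  stopifnot(bin > 0, phi > 0)
  dur_ms <- result$config$duration * 1000
  nb <- ceiling(dur_ms / bin)
  if (!is.null(result$pop_counts)) {
    # exact per-ms population counts recorded by the integrator
    pc <- result$pop_counts
    counts <- as.integer(rowsum(pc, pmin(floor((seq_along(pc) - 1) / bin) + 1L,
                                         nb))[, 1L])
    counts <- c(counts, integer(nb - length(counts)))
  } else {
    tms <- result$raster$time_ms
    counts <- if (length(tms))
      tabulate(pmin(floor(tms / bin) + 1L, nb), nbins = nb) else integer(nb)
  }
  thr <- phi * result$config$n_neurons
  above <- counts > thr
  events <- data.frame(time_ms = numeric(0), peak_count = integer(0))
  if (any(above)) {
    r <- rle(above)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    sel <- which(r$values)
    pk_t <- numeric(length(sel)); pk_c <- integer(length(sel))
    for (k in seq_along(sel)) {
      rng <- s[sel[k]]:e[sel[k]]
      j <- rng[which.max(counts[rng])]
      pk_t[k] <- (j - 0.5) * bin
      pk_c[k] <- counts[j]
    }
    events <- data.frame(time_ms = pk_t, peak_count = pk_c)
  }
  structure(list(bin = bin, phi = phi, counts = counts, events = events,
                 inf_rate = nrow(events) / (result$config$duration / 60),
                 duration_s = result$config$duration),
            class = "inf_series")
}

#' E/I ratio sweep of the spiking network
#'
#' Simulates the network at each excitatory/inhibitory split, `reps`
#' seeds per ratio, scores each run with the INF event rate, and reports
#' per-ratio mean and SD plus the ratio whose mean INF is maximal.
#'
#' @param ratios Two-column matrix (or list of length-2 vectors) of
#'   `(n_excitatory, n_inhibitory)` pairs, each summing to the template's
#'   `n_neurons`. Default: 900:100 down to 100:900 in steps of 100.
#' @param reps Seeds per ratio (default 3).
#' @param config Template [sim_config()].
#' @param seed Base integer seed; run seeds are derived from it.
#' @param phi,bin Passed to [instantaneous_network_firing()].
#' @param verbose Print one line per run.
#' @return An `ei_sweep`: list with `table` (data frame `n_exc`, `n_inh`,
#'   `mean_inf`, `sd_inf`), `runs` (per-run rates), `argmax_exc`.
#' @export
ei_sweep <- function(ratios = NULL, reps = 3, config = sim_config(),
                     seed = 1L, phi = 0.25, bin = 10, verbose = FALSE) {
  if (is.null(ratios)) {
    ex <- seq(900L, 100L, by = -100L)
    ratios <- cbind(ex, config$n_neurons - ex)
  }
  if (is.list(ratios)) ratios <- do.call(rbind, ratios)
  ratios <- matrix(as.integer(ratios), ncol = 2L)
  if (any(rowSums(ratios) != config$n_neurons))
    stop("each ratio must sum to n_neurons")
  stopifnot(reps >= 1)
  runs <- expand.grid(rep = seq_len(reps), row = seq_len(nrow(ratios)))
  rates <- numeric(nrow(runs))
  for (k in seq_len(nrow(runs))) {
    i <- runs$row[k]
    cfg <- config
    cfg$n_excitatory <- ratios[i, 1L]
    cfg$seed <- as.integer(seed) + 1009L * i + runs$rep[k]
    net <- build_network(cfg)
    sim <- simulate_network(net, cfg, record_raster = FALSE)
    rates[k] <- instantaneous_network_firing(sim, bin = bin, phi = phi)$inf_rate
    if (verbose)
      message(sprintf("E/I %d:%d rep %d: INF %.2f events/min",
                      ratios[i, 1L], ratios[i, 2L], runs$rep[k], rates[k]))
  }
  per <- data.frame(n_exc = ratios[runs$row, 1L],
                    n_inh = ratios[runs$row, 2L],
                    rep = runs$rep, inf_rate = rates)
  tab <- do.call(rbind, lapply(seq_len(nrow(ratios)), function(i) {
    r <- rates[runs$row == i]
    data.frame(n_exc = ratios[i, 1L], n_inh = ratios[i, 2L],
               mean_inf = mean(r), sd_inf = stats::sd(r))
  }))
  structure(list(table = tab, runs = per,
                 argmax_exc = tab$n_exc[which.max(tab$mean_inf)]),
            class = "ei_sweep")
}

#' @export
print.ei_sweep <- function(x, ...) {
  cat("<ei_sweep>\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("INF argmax at %d excitatory neurons\n", x$argmax_exc))
  invisible(x)
}

#' Export a simulated raster as a spike-train set
#'
#' Maps neuron ids to channels of a square-ish dummy grid so the MEA
#' metrics modules (burst detection, network bursts, connectivity) can
#' run unchanged on simulated rasters.
#'
#' @param result A `sim_result`.
#' @param pitch Dummy grid pitch in um.
#' @return A [spike_train_set()] with times in seconds.
#' @export
sim_to_spike_trains <- function(result, pitch = 60) {
  n <- result$config$n_neurons
  ncol_ <- ceiling(sqrt(n))
  nrow_ <- ceiling(n / ncol_)
  g <- grid_geometry(nrow_, ncol_, pitch)
  spike_train_set(result$raster$neuron, result$raster$time_ms / 1000,
                  duration = result$config$duration, geometry = g,
                  label = sprintf("sim %d:%d", result$config$n_excitatory,
                                  n - result$config$n_excitatory))
}
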