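test_that("network construction satisfies the structural contract", {
  cfg <- sim_config(n_neurons = 1000, n_excitatory = 800,
                    synapses_per_neuron = 100, seed = 5)
  net <- build_network(cfg)
  expect_equal(dim(net$targets), c(1000L, 100L))
  # no self-connections
  expect_false(any(net$targets == row(net$targets)))
  # inhibitory neurons target excitatory neurons only
  expect_true(all(net$targets[801:1000, ] <= 800))
  # no duplicate targets per neuron
  expect_true(all(apply(net$targets, 1, function(x) !anyDuplicated(x))))
  # delays: excitatory on the configured range, inhibitory fixed at 1 ms
  expect_true(all(net$delays[1:800, ] %in% 1:20))
  expect_true(all(net$delays[801:1000, ] == 1L))
  # weights: +6 excitatory, -5 inhibitory
  expect_true(all(net$weights[1:800, ] == 6))
  expect_true(all(net$weights[801:1000, ] == -5))
  # determinism
  expect_identical(net$targets, build_network(cfg)$targets)
  expect_error(build_network(sim_config(n_neurons = 50, n_excitatory = 40,
                                        synapses_per_neuron = 50)),
               "smaller")
})

test_that("an all-inhibitory network builds and stays nearly silent", {
  cfg <- sim_config(n_neurons = 200, n_excitatory = 0,
                    synapses_per_neuron = 20, duration = 2, warmup = 0,
                    stdp_enabled = FALSE, seed = 2)
  net <- build_network(cfg)
  sim <- simulate_network(net, cfg)
  # only the externally kicked neurons can fire; no propagation
  expect_lt(nrow(sim$raster), 2 * 2000)
})

test_that("a silent configuration produces an empty raster", {
  cfg <- sim_config(n_neurons = 100, n_excitatory = 80,
                    synapses_per_neuron = 10, init_weight_exc = 0,
                    init_weight_inh = 0, input_current = 0,
                    stdp_enabled = FALSE, duration = 2, warmup = 0, seed = 3)
  sim <- simulate_network(build_network(cfg), cfg)
  expect_equal(nrow(sim$raster), 0L)
  expect_equal(instantaneous_network_firing(sim)$inf_rate, 0)
})

test_that("tonic firing under constant drive matches fine-step integration", {
  # two disconnected neurons, one driven by a constant suprathreshold bias
  cfg <- sim_config(n_neurons = 2, n_excitatory = 2,
                    synapses_per_neuron = 1, init_weight_exc = 0,
                    input_current = 0, bias_current = c(10, 0), dt = 0.1,
                    stdp_enabled = FALSE, duration = 10, warmup = 0, seed = 4)
  sim <- simulate_network(build_network(cfg), cfg)
  spikes <- sim$raster$time_ms[sim$raster$neuron == 1]
  expect_equal(sort(unique(sim$raster$neuron)), 1)
  expect_gt(length(spikes), 10)
  # steady-state inter-spike period vs an independent reference
  # integration of the same equations at a 100x finer step
  period <- mean(diff(spikes)[-(1:3)])
  ref <- oracle_izhi_single(I = 10, total_ms = 10000, dt = 0.01)
  ref_period <- mean(diff(ref)[-(1:3)])
  expect_lt(abs(period - ref_period) / ref_period, 0.05)
})

test_that("with STDP disabled weights never change, with STDP they stay capped", {
  cfg <- sim_config(n_neurons = 300, n_excitatory = 240,
                    synapses_per_neuron = 30, duration = 3, warmup = 0,
                    stdp_enabled = FALSE, seed = 6)
  net <- build_network(cfg)
  sim <- simulate_network(net, cfg)
  expect_identical(sim$final_weights, net$weights)
  cfg2 <- sim_config(n_neurons = 300, n_excitatory = 240,
                     synapses_per_neuron = 30, duration = 5, warmup = 0,
                     stdp_enabled = TRUE, seed = 6)
  sim2 <- simulate_network(build_network(cfg2), cfg2)
  expect_true(all(sim2$final_weights[1:240, ] >= 0))
  expect_true(all(sim2$final_weights[1:240, ] <= cfg2$weight_cap))
  # inhibitory weights are fixed
  expect_true(all(sim2$final_weights[241:300, ] == -5))
  expect_false(identical(sim2$final_weights[1:240, ], net$weights[1:240, ]))
})

test_that("simulation is deterministic per seed and conserves spike counts", {
  cfg <- sim_config(n_neurons = 300, n_excitatory = 240,
                    synapses_per_neuron = 30, duration = 4, warmup = 1,
                    seed = 7)
  net <- build_network(cfg)
  s1 <- simulate_network(net, cfg)
  s2 <- simulate_network(net, cfg)
  expect_identical(s1$raster, s2$raster)
  inf <- instantaneous_network_firing(s1)
  expect_equal(sum(inf$counts), nrow(s1$raster))
  # counts-only mode agrees with the full raster
  s3 <- simulate_network(net, cfg, record_raster = FALSE)
  expect_equal(s3$pop_counts, s1$pop_counts)
  expect_equal(instantaneous_network_firing(s3)$inf_rate, inf$inf_rate)
})

test_that("INF counts planted population surges and is monotone in phi", {
  # hand-built raster: 3 surges of 400 synchronous spikes over 1000 neurons
  mk <- function(times_ms) {
    raster <- data.frame(
      neuron = rep(rep(1:400, length(times_ms))),
      time_ms = rep(times_ms, each = 400) + rep(runif(400, 0, 8), length(times_ms)))
    list(raster = raster,
         config = list(n_neurons = 1000L, duration = 10))
  }
  set.seed(8)
  r <- mk(c(1000, 5000, 9000))
  inf <- instantaneous_network_firing(r, bin = 10, phi = 0.25)
  expect_equal(nrow(inf$events), 3L)
  expect_equal(inf$inf_rate, 3 / (10 / 60))
  # phi above the surge amplitude: no events
  expect_equal(nrow(instantaneous_network_firing(r, phi = 0.5)$events), 0L)
  # raising phi never increases the event count
  counts <- vapply(seq(0.05, 0.6, by = 0.05), function(p)
    nrow(instantaneous_network_firing(r, phi = p)$events), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("stationary firing roughly doubles with doubled duration", {
  base <- function(dur) {
    cfg <- sim_config(n_neurons = 500, n_excitatory = 400,
                      synapses_per_neuron = 50, duration = dur, warmup = 2,
                      stdp_enabled = FALSE, seed = 9)
    sim <- simulate_network(build_network(cfg), cfg, record_raster = FALSE)
    sum(sim$pop_counts)
  }
  n1 <- base(8); n2 <- base(16)
  expect_gt(n2 / n1, 2 * 0.85)
  expect_lt(n2 / n1, 2 * 1.15)
})

test_that("simulated rasters convert to analyzable spike-train sets", {
  cfg <- sim_config(n_neurons = 300, n_excitatory = 240,
                    synapses_per_neuron = 30, duration = 4, warmup = 1,
                    seed = 10)
  sim <- simulate_network(build_network(cfg), cfg)
  sts <- sim_to_spike_trains(sim)
  expect_s3_class(sts, "spike_train_set")
  expect_equal(n_spikes(sts), nrow(sim$raster))
  expect_equal(sts$duration, 4)
  r <- mean_firing_rate(sts)
  expect_equal(sum(r) * 4, nrow(sim$raster))
})

test_that("a single-ratio sweep equals a direct simulate + INF call", {
  cfg <- sim_config(n_neurons = 200, n_excitatory = 160,
                    synapses_per_neuron = 20, duration = 3, warmup = 1)
  sw <- ei_sweep(ratios = rbind(c(160L, 40L)), reps = 1, config = cfg,
                 seed = 11)
  cfg2 <- cfg
  cfg2$n_excitatory <- 160L
  cfg2$seed <- 11L + 1009L + 1L
  direct <- instantaneous_network_firing(
    simulate_network(build_network(cfg2), cfg2))
  expect_equal(sw$table$mean_inf, direct$inf_rate)
  expect_true(is.na(sw$table$sd_inf))
  # rerun reproduces the table exactly
  sw2 <- ei_sweep(ratios = rbind(c(160L, 40L)), reps = 1, config = cfg,
                  seed = 11)
  expect_identical(sw$table, sw2$table)
})
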