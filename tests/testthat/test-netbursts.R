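test_that("array firing rate bins and conserves spike counts", {
  g <- small_grid(4)
  empty <- spike_train_set(integer(0), numeric(0), 1, g)
  expect_true(all(array_firing_rate(empty)$count == 0))
  # 100 spikes in one 25 ms bin read 4000 spikes/s
  s <- spike_train_set(rep(1:10, 10), seq(0.0501, 0.0749, length.out = 100), 1, g)
  ar <- array_firing_rate(s, bin = 0.025)
  expect_equal(ar$rate[3], 4000)
  expect_equal(sum(ar$rate) * 0.025, 100)
  # conservation on a random fixture with non-divisible duration
  x <- generate_background(g, 10.37, rate_map = 5, seed = 3)
  ar2 <- array_firing_rate(x, bin = 0.025)
  expect_equal(sum(ar2$count), n_spikes(x))
  expect_equal(nrow(ar2), ceiling(10.37 / 0.025))
})

make_nb_fixture <- function(seed = 21, duration = 120, nb_rate = 5) {
  g <- small_grid(8)
  base <- generate_background(g, duration, rate_map = 0.5, seed = seed)
  generate_network_bursts(base, nb_rate = nb_rate, seed = seed + 1)
}

test_that("network-burst detection recovers planted bursts", {
  fx <- make_nb_fixture()
  nbs <- detect_network_bursts(fx$spikes)
  planted <- fx$truth$nb_times
  # every planted NB matched by a detected interval within 100 ms
  hits <- vapply(planted, function(t)
    any(nbs$start - 0.1 <= t & t <= nbs$end + 0.1), logical(1))
  expect_gte(mean(hits), 0.9)
  expect_equal(network_burst_rate(nbs), nrow(nbs) / 2)
  expect_true(all(nbs$start < nbs$end))
  # disjoint after merging
  if (nrow(nbs) > 1)
    expect_true(all(nbs$start[-1] >= nbs$end[-nrow(nbs)]))
})

test_that("bursts closer than the merge gap are merged", {
  g <- small_grid(6)
  mk_burst <- function(t0) {
    ch <- rep(1:36, each = 5)
    tt <- t0 + runif(180, 0, 0.05)
    list(ch = ch, tt = tt)
  }
  set.seed(4)
  b1 <- mk_burst(10); b2 <- mk_burst(10.1)   # 50 ms apart end-to-start
  bg <- generate_background(g, 60, rate_map = 0.5, seed = 5)
  s <- merge_spike_trains(bg, spike_train_set(
    c(b1$ch, b2$ch), c(b1$tt, b2$tt), 60, g))
  one <- detect_network_bursts(s, merge_gap = 0.1)
  two <- detect_network_bursts(s, merge_gap = 0.01)
  expect_equal(nrow(one), 1L)
  expect_equal(nrow(two), 2L)
})

test_that("detection equals the brute-force binned-matrix oracle", {
  fx <- make_nb_fixture(seed = 33, duration = 60, nb_rate = 4)
  got <- detect_network_bursts(fx$spikes)
  want <- oracle_network_bursts(fx$spikes)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
})

test_that("raising the rate threshold never increases the NB count", {
  fx <- make_nb_fixture(seed = 44, duration = 60, nb_rate = 4)
  thr <- seq(50, 2000, length.out = 8)
  counts <- vapply(thr, function(th)
    nrow(detect_network_bursts(fx$spikes, rate_threshold = th)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("no active channels yields an empty result with a warning", {
  g <- small_grid(3)
  s <- spike_train_set(1L, 0.5, 100, g)   # 0.01 Hz, below threshold
  expect_warning(nbs <- detect_network_bursts(s), "no active channels")
  expect_equal(nrow(nbs), 0L)
})

test_that("center-of-activity trajectories sit at the activity centroid", {
  g <- small_grid(4)   # positions 0..180 um, centroid (90, 90)
  # spatially uniform firing: CA at the grid centroid in every bin
  ch <- rep(1:16, 10)
  tt <- rep(seq(1.001, 1.045, length.out = 10), each = 16)
  s <- spike_train_set(ch, tt, 3, g)
  cat1 <- center_of_activity_trajectory(s, list(start = 1, end = 1.05))
  expect_true(all(abs(cat1$x - 90) < 1e-9))
  expect_true(all(abs(cat1$y - 90) < 1e-9))
  # point mass: CA constant at that channel's position
  s2 <- spike_train_set(rep(7L, 20), seq(1.001, 1.049, length.out = 20), 3, g)
  cat2 <- center_of_activity_trajectory(s2, list(start = 1, end = 1.05))
  p7 <- channel_positions(g, 7L)
  expect_true(all(cat2$x == p7$x & cat2$y == p7$y))
  # CAT points are convex combinations of electrode positions
  fx <- make_nb_fixture(seed = 55, duration = 60, nb_rate = 3)
  nbs <- detect_network_bursts(fx$spikes)
  skip_if(nrow(nbs) == 0)
  tr <- center_of_activity_trajectory(fx$spikes, nbs[1, ])
  lim <- (8 - 1) * 60
  expect_true(all(tr$x >= 0 & tr$x <= lim & tr$y >= 0 & tr$y <= lim))
  expect_true(all(tr$t >= nbs$start[1] & tr$t <= nbs$end[1]))
  expect_error(center_of_activity_trajectory(fx$spikes,
                                             list(start = -1, end = 2)),
               "outside")
})

test_that("CAT origin tracks the planted propagation origin", {
  g <- grid_geometry(20, 20, 60)
  base <- generate_background(g, 120, rate_map = 0.3, seed = 61)
  fx <- generate_network_bursts(base, nb_rate = 3, participation = 0.8,
                                propagation_speed = 20, burst_rate = 200,
                                nb_duration = 0.15, origin_margin = 300,
                                seed = 62)
  nbs <- detect_network_bursts(fx$spikes, min_participation = 0.1)
  hits <- 0; total <- 0
  for (k in seq_along(fx$truth$nb_times)) {
    t0 <- fx$truth$nb_times[k]
    i <- which(nbs$start - 0.1 <= t0 & t0 <= nbs$end)
    if (!length(i)) next
    total <- total + 1
    tr <- center_of_activity_trajectory(fx$spikes, nbs[i[1], ])
    d0 <- sqrt((tr$x[1] - fx$truth$nb_origin$x[k])^2 +
                 (tr$y[1] - fx$truth$nb_origin$y[k])^2)
    if (d0 <= 2 * g$pitch) hits <- hits + 1
    # the trajectory moves
    expect_gt(sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2)), 0)
  }
  expect_gte(total, 4)
  expect_gte(hits / total, 0.8)
})
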