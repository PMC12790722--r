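test_that("session validation enforces the pulse protocol invariants", {
  g <- small_grid(4)
  s <- generate_background(g, 20, rate_map = 1, seed = 1)
  expect_error(stimulation_session(s, c(2, 1), 1L), "increasing")
  expect_error(stimulation_session(s, c(1, 25), 1L), "within the recording")
  expect_error(stimulation_session(s, c(1, 1.2), 1L), "separated")
  expect_error(stimulation_session(s, 1, 999L), "outside geometry")
  sess <- stimulation_session(s, c(1, 2, 3), 1L)
  expect_s3_class(sess, "stimulation_session")
})

test_that("planted excitatory and suppressive responses are recovered with sign", {
  g <- grid_geometry(6, 6, 60)
  stim <- 15L
  exc_k <- make_response_kernel(amplitude = 400, latency_peak = 0.007,
                                latency_sd = 0.002, distance_scale = Inf,
                                max_distance = 1)   # only the stim site
  fx <- generate_stim_session(g, stim, n_pulses = 25, kernel = exc_k,
                              baseline_rate = 1, seed = 41)
  rm <- evoked_response(fx$session, seed = 42)
  # the stimulated channel is positive-significant in the 5-10 ms bin
  expect_equal(rm$significance[as.character(stim), 1L], 1L)
  # and is (nearly) the only strongly flagged channel in that bin
  expect_lte(sum(rm$significance[, 1L] == 1L), 5L)
  # suppressive kernel on a brisk baseline
  sup_k <- make_response_kernel(amplitude = -100, latency_peak = 0.05,
                                latency_sd = 0.05, distance_scale = 200)
  fx2 <- generate_stim_session(g, stim, n_pulses = 25, kernel = sup_k,
                               baseline_rate = 20, seed = 43)
  rm2 <- evoked_response(fx2$session, seed = 44)
  expect_equal(rm2$significance[as.character(stim), "40-60ms"], -1L)
  expect_gt(sum(rm2$significance == -1L), sum(rm2$significance == 1L))
})

test_that("the response map is invariant under joint time translation", {
  g <- small_grid(5)
  k <- make_response_kernel(amplitude = 150, distance_scale = 150)
  fx <- generate_stim_session(g, 13L, n_pulses = 12, kernel = k, seed = 51)
  s <- fx$session
  shift <- 3.21
  s2 <- stimulation_session(
    spike_train_set(s$spikes$events$channel, s$spikes$events$time + shift,
                    s$spikes$duration + shift, g),
    s$pulse_times + shift, s$stim_channels)
  r1 <- evoked_response(s, seed = 7)
  r2 <- evoked_response(s2, seed = 7)
  expect_equal(r1$mean, r2$mean)
  expect_equal(r1$significance, r2$significance)
})

test_that("global response curve normalizes positive evoked activity", {
  edges <- c(5, 10, 20, 40, 60, 100, 150) / 1000
  mean_mat <- matrix(0, 3, 6)
  sig <- matrix(0L, 3, 6)
  mean_mat[1, 1] <- 2; sig[1, 1] <- 1L        # point mass in first bin
  m1 <- fake_response_map(1:3, edges, mean_mat, sig)
  expect_equal(unname(global_response_curve(m1)), c(1, 0, 0, 0, 0, 0))
  # uniform planting across bins
  mean_mat2 <- matrix(1, 3, 6); sig2 <- matrix(1L, 3, 6)
  m2 <- fake_response_map(1:3, edges, mean_mat2, sig2)
  expect_equal(unname(global_response_curve(m2)), rep(1 / 6, 6))
  expect_equal(sum(global_response_curve(m2)), 1)
  # no positive responses: zero curve with a warning
  m0 <- fake_response_map(1:3, edges, matrix(0, 3, 6), matrix(0L, 3, 6))
  expect_warning(z <- global_response_curve(m0), "no positive")
  expect_true(all(z == 0))
})

test_that("dispersion index equals the brute-force mean distance", {
  g <- grid_geometry(9, 9, 60)
  stim <- 41L                                 # grid centre
  edges <- c(5, 10, 20, 40, 60, 100, 150) / 1000
  # single responsive channel at a known distance
  sig <- matrix(0L, 81, 6); sig[44, 1] <- 1L  # 3 columns right: 180 um
  m <- fake_response_map(1:81, edges, matrix(1, 81, 6), sig)
  d <- dispersion_index(m, g, stim)
  expect_equal(d$mean_distance[1], 180)
  expect_equal(d$n_responsive[1], 1L)
  expect_true(is.na(d$mean_distance[2]))
  # ring of radius 2 pitches around the centre
  pos <- channel_positions(g)
  centre <- channel_positions(g, stim)
  dist_all <- sqrt((pos$x - centre$x)^2 + (pos$y - centre$y)^2)
  ring <- which(abs(dist_all - 120) < 1e-9)
  sig2 <- matrix(0L, 81, 6); sig2[ring, 3] <- 1L
  m2 <- fake_response_map(1:81, edges, matrix(1, 81, 6), sig2)
  expect_equal(dispersion_index(m2, g, stim)$mean_distance[3], 120)
  # random patterns against the quadratic oracle, both modes
  set.seed(61)
  for (rep in 1:3) {
    sig3 <- matrix(sample(c(0L, 1L, -1L), 81 * 6, TRUE, c(0.8, 0.1, 0.1)),
                   81, 6)
    m3 <- fake_response_map(1:81, edges, matrix(1, 81, 6), sig3)
    d3 <- dispersion_index(m3, g, c(5L, 41L))
    for (b in 1:6) {
      resp <- which(sig3[, b] != 0L)
      want <- oracle_dispersion(resp, g, c(5L, 41L))
      if (is.na(want)) expect_true(is.na(d3$mean_distance[b]))
      else expect_equal(d3$mean_distance[b], want)
    }
    dp <- dispersion_index(m3, g, 41L, mode = "pairwise")
    b1 <- which(colSums(sig3 != 0L) >= 2)[1]
    if (!is.na(b1)) {
      resp <- which(sig3[, b1] != 0L)
      rp <- channel_positions(g, resp)
      expect_equal(dp$mean_distance[b1], mean(dist(cbind(rp$x, rp$y))))
    }
  }
})

test_that("a spatially growing planted response yields a rising dispersion", {
  g <- grid_geometry(12, 12, 60)
  stim <- 66L
  # activation radius grows with latency
  kern <- function(distance_um, latency_s)
    ifelse(distance_um <= 3000 * latency_s + 60, 150, 0)
  fx <- generate_stim_session(g, stim, n_pulses = 25, kernel = kern,
                              baseline_rate = 0.5, seed = 71)
  rm <- evoked_response(fx$session, seed = 72)
  d <- dispersion_index(rm, g, stim, signs = 1L)
  v <- d$mean_distance[!is.na(d$mean_distance)]
  expect_gte(length(v), 3)
  expect_gt(v[length(v)], v[1])
})

test_that("multi-electrode stimulation evokes network bursts only when it propagates", {
  g <- grid_geometry(10, 10, 60)
  stim <- c(34L, 35L, 44L, 45L, 55L, 56L, 66L)
  # propagating kernel: strong response over most of the grid
  prop_k <- make_response_kernel(amplitude = 500, latency_peak = 0.02,
                                 latency_sd = 0.01, distance_scale = Inf)
  fx <- generate_stim_session(g, stim, n_pulses = 10, kernel = prop_k,
                              baseline_rate = 1, pulse_interval = 2,
                              seed = 81)
  rep_prop <- detect_evoked_nb(fx$session, window = 0.5)
  expect_gte(rep_prop$n_evoked, 9)
  # local-only kernel: response confined to the stimulated channels
  loc_k <- make_response_kernel(amplitude = 500, latency_peak = 0.02,
                                latency_sd = 0.01, distance_scale = Inf,
                                max_distance = 50)
  fx2 <- generate_stim_session(g, stim, n_pulses = 10, kernel = loc_k,
                               baseline_rate = 1, pulse_interval = 2,
                               seed = 82)
  rep_loc <- detect_evoked_nb(fx2$session, window = 0.5)
  expect_equal(rep_loc$n_evoked, 0L)
  # no pulses: empty report
  s0 <- stimulation_session(fx$session$spikes, numeric(0), stim)
  expect_equal(nrow(detect_evoked_nb(s0)$per_pulse), 0L)
})

test_that("stimulation channels are the most active, ties to lower ids", {
  g <- small_grid(4)
  rates <- c(5, 3, 3, 8, rep(0.5, 12))
  x <- generate_background(g, 300, rates, seed = 91)
  expect_equal(select_stim_channels(x, k = 1), 4L)
  top <- select_stim_channels(x, k = 4)
  expect_setequal(top, c(1L, 2L, 3L, 4L))
  # equal planted rates: deterministic fixture with exact ties
  y <- spike_train_set(rep(1:16, each = 30),
                       rep(seq(0.5, 295, length.out = 30), 16), 300, g)
  expect_equal(select_stim_channels(y, k = 7), 1:7)
  expect_warning(sel <- select_stim_channels(x, k = 20), "fewer than k")
  expect_lte(length(sel), 16)
})
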