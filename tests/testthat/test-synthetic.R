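# Synthetic-session generator: geometry, determinism, linearity, ground
# truth of the evoked model.

test_that("grid geometry assigns unique positions and labels on the stated axes", {
  g <- grid_geometry()
  expect_equal(nrow(g$channels), 60)
  expect_false(any(duplicated(g$channels[, c("row", "col")])))
  expect_false(any(duplicated(g$channels[, c("x", "y")])))
  expect_equal(diff(range(g$channels$x)), 2000)  # 6 rows x 400 um
  expect_equal(diff(range(g$channels$y)), 3600)  # 10 cols x 400 um
  # row A is the most caudal (largest x), column 1 the most medial
  a1 <- g$channels[g$channels$label == "A1", ]
  expect_equal(c(a1$x, a1$y), c(2000, 3600))
  expect_equal(channel_index("C5", g),
               which(g$channels$row == 3 & g$channels$col == 5))
  expect_error(channel_index("Z9", g), "unknown")
  expect_error(grid_geometry(1, 10), "n_rows")
})

test_that("probe geometry spaces sites along depth and rejects degenerate probes", {
  p <- probe_geometry()
  expect_equal(p$n_sites, 16)
  expect_equal(diff(p$channels$depth), rep(50, 15))
  expect_error(probe_geometry(2), "n_sites")
})

test_that("identical scenario seeds give bit-identical sessions", {
  sc <- bc_scenario(noise_sd = 8, latency_jitter_sd = 1, n_trials = 2, rng_seed = 7L)
  r1 <- simulate_grid_session(sc, fs = 2000)
  r2 <- simulate_grid_session(sc, fs = 2000)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$events, r2$events)
  l1 <- simulate_laminar_session(sc)
  l2 <- simulate_laminar_session(sc)
  expect_identical(l1$data, l2$data)
})

test_that("noise-free evoked signal is linear in component amplitude", {
  sc1 <- quiet_bc(n_trials = 2)
  sc2 <- quiet_bc(n_trials = 2)
  for (j in seq_along(sc2$components))
    sc2$components[[j]]$peak_amplitude <- 2 * sc1$components[[j]]$peak_amplitude
  r1 <- simulate_grid_session(sc1, fs = 2000)
  r2 <- simulate_grid_session(sc2, fs = 2000)
  expect_equal(r2$data, 2 * r1$data, tolerance = 1e-12)
})

test_that("a single noise-free component peaks at its latency with the configured amplitude", {
  g <- grid_geometry()
  centre_ch <- channel_index("D5", g)
  ctr <- c(g$channels$x[centre_ch], g$channels$y[centre_ch])
  cfg <- scenario_config(
    components = list(component_spec("P", latency = 42, temporal_width = 5,
                                     peak_amplitude = 50, center = ctr,
                                     footprint_sigma = 400)),
    n_trials = 1, noise_sd = 0, latency_jitter_sd = 0, rng_seed = 3L)
  rec <- simulate_grid_session(cfg, g, fs = 2000)
  ev <- rec$events[1]
  i_pk <- which.max(rec$data[centre_ch, ])
  # the continuous-time peak can fall up to half a sample off the grid
  expect_equal(max(rec$data[centre_ch, ]), 50, tolerance = 1e-3)
  expect_lt(abs((i_pk - 1) / 2000 - (ev + 0.042)), 1e-3)
  # half-maximum spatial contour: gain 1 at the centre, 1/2 at sigma*sqrt(2 ln 2)
  d <- sqrt((g$channels$x - ctr[1])^2 + (g$channels$y - ctr[2])^2)
  near_half <- which.min(abs(d - 400 * sqrt(2 * log(2))))
  gain <- rec$data[near_half, i_pk] / max(rec$data[centre_ch, ])
  expect_equal(gain, exp(-d[near_half]^2 / (2 * 400^2)), tolerance = 1e-6)
})

test_that("ablated scenarios carry no evoked signal", {
  sc <- quiet_bc(n_trials = 2, ablated = TRUE)
  rec <- simulate_grid_session(sc, fs = 2000)
  expect_equal(max(abs(rec$data)), 0)
})

test_that("trial-averaged noise amplitude shrinks like 1/sqrt(n)", {
  gg <- grid_geometry(2, 2, 400)
  rms <- vapply(c(4L, 16L, 64L), function(n) {
    cfg <- scenario_config(
      components = list(component_spec("P", 42, 5, 1, c(0, 0), footprint_sigma = 300)),
      n_trials = n, isi_range = c(1.6, 1.6), noise_sd = 10,
      latency_jitter_sd = 0, ablated = TRUE, rng_seed = 11L)
    rec <- simulate_grid_session(cfg, gg, fs = 2000)
    avg <- average_epochs(epoch_recording(rec, pre = 0.1, post = 0.2))
    sqrt(mean(avg$data^2))
  }, numeric(1))
  expect_equal(rms * sqrt(c(4, 16, 64)) / 10, rep(1, 3), tolerance = 0.2)
})

test_that("developmental latency model evaluates the exponential decay", {
  m <- age_latency_model(a = 30, b = 0.3, c = 15, reference_age = 8)
  expect_equal(latency_at_age(m, 8), 45)
  expect_equal(latency_at_age(m, 1e6), 15, tolerance = 1e-8)
  flat <- age_latency_model(a = 30, b = 0, c = 15)
  expect_equal(latency_at_age(flat, c(8, 12, 16)), rep(45, 3))
  expect_error(latency_at_age(m, 5), "age")
})

test_that("laminar sessions realize the configured dipole and spiking", {
  sc <- quiet_bc(n_trials = 1, rng_seed = 4L)
  rec <- simulate_laminar_session(sc)
  gt <- rec$ground_truth
  i_t <- round((rec$events[1] + gt$sink_latency / 1000) * rec$fs) + 1
  expect_equal(which.min(rec$data[, i_t]), gt$sink_site)
  # zero spike rate -> no spikes anywhere, empty PSTH
  sc0 <- quiet_bc(n_trials = 2, rng_seed = 5L)
  sc0$laminar$spikes_per_trial <- 0
  rec0 <- simulate_laminar_session(sc0)
  expect_true(all(lengths(rec0$ground_truth$spike_times) == 0))
  ph <- psth(lapply(rec0$ground_truth$spike_times, function(tt) list(times = tt)),
             rec0$events)
  expect_equal(sum(ph$counts), 0)
  expect_error(simulate_laminar_session(sc, fs = 5000), "20 kHz")
})

test_that("off-grid component centres warn instead of failing", {
  g <- grid_geometry()
  cfg <- scenario_config(
    components = list(component_spec("P", 42, 5, 10, c(-5000, -5000),
                                     footprint_sigma = 300)),
    n_trials = 1, noise_sd = 0, latency_jitter_sd = 0, rng_seed = 1L)
  expect_warning(simulate_grid_session(cfg, g, fs = 2000), "outside the grid hull")
  expect_error(simulate_grid_session(cfg, g, fs = 500), "2000")
})
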