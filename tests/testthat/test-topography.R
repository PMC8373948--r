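# Component peaks, interpolated maps, half-maximum regions, overlaps,
# polar displacements.

test_that("component peaks are recovered from a noise-free biphasic session", {
  sc <- quiet_bc(n_trials = 2)
  pp <- preprocess(simulate_grid_session(sc, fs = 4000))
  pk <- find_component_peaks(pp$avg)
  expect_false(is.null(pk$P))
  expect_false(is.null(pk$N))
  g <- pp$avg$geometry
  # best channel is the electrode at the configured P footprint centre
  ctr <- sc$components[[1]]$center
  d <- sqrt((g$channels$x - ctr[1])^2 + (g$channels$y - ctr[2])^2)
  expect_equal(pk$P$channel, which.min(d))
  expect_lt(abs(pk$P$latency - sc$components[[1]]$latency), 1)
  expect_lt(abs(pk$N$latency - sc$components[[2]]$latency), 1)
  expect_gt(pk$P$amplitude, 0)
  expect_lt(pk$N$amplitude, 0)
  expect_gt(pk$N$latency, pk$P$latency)
})

test_that("ablated and pure-noise sessions report no response", {
  sc <- bc_scenario(noise_sd = 10, latency_jitter_sd = 0, n_trials = 8,
                    rng_seed = 5L, ablated = TRUE)
  pp <- preprocess(simulate_grid_session(sc, fs = 2000), target_fs = 2000)
  pk <- find_component_peaks(pp$avg)
  expect_null(pk$P)
  expect_null(pk$N)
})

test_that("window amplitude averaging matches the analytic pulse window mean", {
  g <- grid_geometry()
  fs <- 2000
  t_ms <- (seq_len(3000) - 1 - 1000) / fs * 1000
  width <- 5
  pulse <- 40 * exp(-(t_ms - 50)^2 / (2 * (width / sqrt(2 * log(2)))^2))
  data <- matrix(0, 60, 3000)
  data[7, ] <- pulse
  data[9, ] <- 3  # constant channel
  avg <- make_avg(data, fs, 0.5, 1.0, g)
  pk <- structure(list(label = "P", channel = 7, latency = 50, amplitude = 40),
                  class = "component_peak")
  vals <- window_amplitude_map(avg, pk, half_window = 1)
  analytic <- 40 * sepmap:::pulse_window_mean(width, 1)
  expect_lt(vals[7], 40)  # averaging bias
  # discrete 5-sample mean at 2 kHz vs the continuous window integral
  expect_equal(vals[7], analytic, tolerance = 0.01)
  expect_equal(vals[9], 3)
  # degenerate window: the instantaneous sample at the peak
  expect_equal(window_amplitude_map(avg, pk, half_window = 0)[7], 40)
})

test_that("map interpolation is exact at electrodes and reproduces low-order fields", {
  g <- grid_geometry()
  ch <- g$channels
  flat <- interpolate_map(rep(4.2, 60), g, step = 100)
  expect_lt(max(abs(flat$field - 4.2)), 1e-9)
  bil <- 1 + 0.002 * ch$x - 0.0005 * ch$y
  m <- interpolate_map(bil, g, step = 100)
  xs <- (seq_len(nrow(m$field)) - 1) * 100
  ys <- (seq_len(ncol(m$field)) - 1) * 100
  truth <- outer(1 + 0.002 * xs, 0.0005 * ys, "-")
  expect_lt(max(abs(m$field - truth)), 1e-9)
  # electrode-position exactness for a generic smooth field
  vals <- exp(-((ch$x - 966.8)^2 + (ch$y - 2077.8)^2) / (2 * 428^2))
  mg <- interpolate_map(vals, g, step = 10)
  px <- ch$x / 10 + 1
  py <- ch$y / 10 + 1
  expect_lt(max(abs(mg$field[cbind(px, py)] - vals) / max(abs(vals))), 1e-6)
  expect_warning(interpolate_map(vals, g, step = 500), "pitch")
})

test_that("map peak location converges with pixel step", {
  g <- grid_geometry()
  ch <- g$channels
  vals <- exp(-((ch$x - 966.8)^2 + (ch$y - 2077.8)^2) / (2 * 428^2))
  l10 <- locate_peak(interpolate_map(vals, g, step = 10), "P")
  l1 <- locate_peak(interpolate_map(vals, g, step = 1), "P")
  expect_lte(abs(l10$x - l1$x), 10)
  expect_lte(abs(l10$y - l1$y), 10)
})

test_that("peak localization follows the sign convention and tie rule", {
  g <- grid_geometry()
  ch <- g$channels
  vals <- exp(-((ch$x - 800)^2 + (ch$y - 2000)^2) / (2 * 500^2))
  loc <- locate_peak(interpolate_map(vals, g, step = 10), "P")
  expect_equal(c(loc$x, loc$y), c(800, 2000))
  nloc <- locate_peak(interpolate_map(-vals, g, step = 10), "N")
  expect_equal(c(nloc$x, nloc$y), c(800, 2000))
  expect_warning(tie <- locate_peak(interpolate_map(rep(1, 60), g, 100), "P"),
                 "tied")
  expect_equal(c(tie$x, tie$y), c(0, 0))
})

test_that("half-maximum areas match closed forms for Gaussian and disk footprints", {
  g <- grid_geometry()
  ch <- g$channels
  # isotropic Gaussian, sigma = 505 um, fully inside the hull: A = 2 pi ln2 sigma^2
  vals <- 100 * exp(-((ch$x - 1000)^2 + (ch$y - 1800)^2) / (2 * 505^2))
  m <- interpolate_map(vals, g, step = 10)
  reg <- half_width_region(m, locate_peak(m, "P"))
  expect_false(reg$truncated)
  expect_equal(reg$area_mm2, 2 * pi * log(2) * 0.505^2, tolerance = 0.02)
  # area grows strictly with footprint scale
  areas <- vapply(c(420, 470, 505, 540), function(s) {
    v <- 100 * exp(-((ch$x - 1000)^2 + (ch$y - 1800)^2) / (2 * s^2))
    mm <- interpolate_map(v, g, step = 20)
    half_width_region(mm, locate_peak(mm, "P"))$area_mm2
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("half-maximum region keeps only the peak-connected lobe and flags truncation", {
  g <- grid_geometry()
  ch <- g$channels
  two <- 100 * exp(-((ch$x - 800)^2 + (ch$y - 1000)^2) / (2 * 300^2)) +
         80 * exp(-((ch$x - 1200)^2 + (ch$y - 3000)^2) / (2 * 300^2))
  m <- interpolate_map(two, g, step = 20)
  loc <- locate_peak(m, "P")
  reg <- half_width_region(m, loc)
  # the satellite lobe near y = 3000 must not be included
  ys <- (seq_len(ncol(reg$mask)) - 1) * 20
  expect_equal(sum(reg$mask[, ys > 2400]), 0)
  # a footprint centred on the hull edge is truncated
  edge <- 100 * exp(-((ch$x - 0)^2 + (ch$y - 1800)^2) / (2 * 400^2))
  me <- interpolate_map(edge, g, step = 20)
  expect_true(half_width_region(me, locate_peak(me, "P"))$truncated)
})

test_that("pixel-counted disk overlaps match the circle-lens closed form", {
  for (case in list(c(r1 = 450, r2 = 594, d = 339),
                    c(r1 = 594, r2 = 594, d = 0),
                    c(r1 = 300, r2 = 500, d = 850),
                    c(r1 = 374, r2 = 594, d = 500))) {
    A <- make_disk_region(900, 1500, case["r1"], step = 20)
    B <- make_disk_region(900 + case["d"], 1500, case["r2"], step = 20)
    ov <- region_overlap(A, B)
    truth <- unname(lens_area(case[["r1"]], case[["r2"]], case[["d"]]) / 1e6)
    if (truth == 0) expect_equal(ov$intersection_area_mm2, 0)
    else expect_equal(ov$intersection_area_mm2, truth, tolerance = 0.01)
    expect_equal(ov$intersection_area_mm2,
                 region_overlap(B, A)$intersection_area_mm2)
  }
  A <- make_disk_region(900, 1500, 300, step = 20)
  expect_equal(region_overlap(A, A)$frac_of_a, 1)
  expect_equal(region_overlap(A, A)$frac_of_b, 1)
  B <- make_disk_region(900, 3000, 300, step = 20)
  expect_equal(region_overlap(A, B)$frac_of_a, 0)
  A10 <- make_disk_region(900, 1500, 300, step = 10)
  expect_error(region_overlap(A, A10), "different pixel grids")
})

test_that("peak displacements follow the caudal-zero polar convention", {
  loc <- function(x, y) structure(list(x = x, y = y, amplitude = 1),
                                  class = "peak_location")
  expect_equal(peak_displacement(loc(0, 0), loc(250, 0))$theta, 0)
  expect_equal(peak_displacement(loc(0, 0), loc(0, -250))$theta, -90)
  d <- peak_displacement(loc(0, 0), loc(300, -400))
  expect_equal(d$r, 500)
  expect_equal(d$theta, atan2(-400, 300) * 180 / pi)
  expect_message(z <- peak_displacement(loc(5, 5), loc(5, 5)), "undefined")
  expect_equal(z$r, 0)
  expect_true(is.na(z$theta))
})

test_that("a channel-constant offset before referencing leaves peak locations unchanged", {
  sc <- quiet_bc(n_trials = 2)
  rec <- simulate_grid_session(sc, fs = 2000)
  rec2 <- rec
  rec2$data <- rec2$data + 25
  for (r in list(rec, rec2)) {
    pp <- preprocess(r, target_fs = 2000)
    pk <- find_component_peaks(pp$avg)
    tp <- component_topography(pp$avg, pk$P, step = 20)
    if (identical(r, rec)) base_loc <- tp$location
    else expect_equal(c(tp$location$x, tp$location$y), c(base_loc$x, base_loc$y))
  }
})
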