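# Preprocessing chain: onset detection, downsampling, epoching,
# referencing, baseline correction, bad-channel replacement, averaging.

test_that("stimulus onsets are detected once per pulse and respect the refractory period", {
  fs <- 1000
  trace <- numeric(40 * fs)
  starts <- seq(2, 38, by = 4)  # 10 pulses, 4 s apart
  for (s in starts) trace[(s * fs + 1):(s * fs + 50)] <- 1
  on <- detect_stimulus_onsets(trace, threshold = 0.5, refractory = 1, fs = fs)
  expect_equal(on, starts)
  # ringing re-crossing inside the refractory window counts once
  ring <- numeric(fs)
  ring[101:110] <- 1; ring[151:160] <- 1
  expect_length(detect_stimulus_onsets(ring, 0.5, refractory = 1, fs = fs), 1)
  expect_length(detect_stimulus_onsets(numeric(fs), 0.5, 1, fs), 0)
  expect_length(detect_stimulus_onsets(numeric(0), 0.5, 1, fs), 0)
  expect_error(detect_stimulus_onsets(c(1, NA), 0.5, 1, fs), "non-finite")
})

test_that("downsampling decimates with anti-aliasing and preserves DC", {
  g <- probe_geometry(3)
  fs <- 20000
  const <- recording(matrix(7.5, 3, 2 * fs), fs, g)
  dn <- downsample_recording(const, 2000)
  expect_equal(dn$fs, 2000)
  expect_equal(ncol(dn$data), ncol(const$data) / 10)
  expect_equal(max(abs(dn$data - 7.5)), 0)
  tt <- seq_len(5 * fs) / fs
  tone <- sin(2 * pi * 1500 * tt)  # above the 1 kHz target Nyquist
  att <- 20 * log10(sd(downsample_recording(
    recording(rbind(tone, tone, tone), fs, g), 2000)$data[1, ]) / sd(tone))
  expect_lt(att, -20)
  expect_error(downsample_recording(const, 40000), "exceeds")
  expect_error(downsample_recording(const, 1500), "divide")
})

test_that("epoching aligns trials to the stimulus and drops incomplete windows", {
  g <- probe_geometry(3)
  fs <- 2000
  n <- 20 * fs
  data <- matrix(0, 3, n)
  events <- c(0.1, 4, 8, 12, 19.8)  # first lacks pre, last lacks post
  for (ev in events[2:4]) data[, round(ev * fs) + 1] <- 1  # pulse at stimulus time
  rec <- recording(data, fs, g, events)
  expect_message(ep <- epoch_recording(rec, pre = 0.5, post = 1.0), "dropping 2")
  expect_equal(dim(ep$data), c(3, 3, 3000))
  peak_idx <- apply(ep$data[, 1, ], 1, which.max)
  expect_equal(peak_idx, rep(0.5 * fs + 1, 3))  # same post-stimulus sample each trial
  expect_error(epoch_recording(rec, events = 0.01, pre = 0.5, post = 1), "complete epoch")
})

test_that("average reference zeroes the channel mean and is idempotent", {
  g <- probe_geometry(3)
  set.seed(1)
  ep <- make_epochs(array(rnorm(2 * 3 * 40, mean = 3), c(2, 3, 40)), 100, 0.2, 0.2, g)
  ref <- average_reference(ep)
  expect_lt(max(abs(apply(ref$data, c(1, 3), mean))), 1e-10)
  expect_equal(average_reference(ref)$data, ref$data, tolerance = 1e-12)
  # two channels [2, 0] at a sample -> [1, -1]
  two <- make_epochs(array(c(2, 0), c(1, 2, 1)), 100, 0.2, 0.2, g)
  expect_equal(as.numeric(average_reference(two)$data), c(1, -1))
  one_ch <- make_epochs(array(1, c(2, 1, 10)), 100, 0.2, 0.2, g)
  expect_error(average_reference(one_ch), "one channel")
})

test_that("baseline correction removes per-trial offsets exactly and is idempotent", {
  g <- probe_geometry(3)
  set.seed(2)
  base <- array(rnorm(2 * 3 * 50), c(2, 3, 50))
  offs <- array(rep(c(5, -2, 1, 4, 0, -3), each = 1), c(2, 3))
  ep <- make_epochs(base + array(offs, c(2, 3, 50)), 100, 0.25, 0.25, g)
  bc <- baseline_correct(ep)
  n_pre <- 25
  expect_lt(max(abs(rowMeans(bc$data[, , 1:n_pre], dims = 2))), 1e-10)
  expect_equal(baseline_correct(bc)$data, bc$data, tolerance = 1e-12)
})

test_that("bad channels are replaced by the mean of their good neighbours", {
  g <- grid_geometry(3, 3, 400)
  n_t <- 10
  v <- sin(seq_len(n_t))
  data <- array(0, c(2, 9, n_t))
  centre <- channel_index("B2", g)
  nb <- c("A2", "B1", "B3", "C2")
  for (lab in nb) data[, channel_index(lab, g), ] <- rep(v, each = 2)
  ep <- make_epochs(data, 100, 0.05, 0.05, g)
  rep_ep <- replace_bad_channels(ep, "B2")
  expect_equal(rep_ep$data[1, centre, ], v, tolerance = 1e-12)
  # corner channel averages its 2 existing neighbours
  data2 <- array(0, c(1, 9, n_t))
  data2[, channel_index("A2", g), ] <- 2
  data2[, channel_index("B1", g), ] <- 4
  ep2 <- make_epochs(data2, 100, 0.05, 0.05, g)
  expect_equal(replace_bad_channels(ep2, "A1")$data[1, channel_index("A1", g), ],
               rep(3, n_t))
  # identity on an empty bad set
  expect_identical(replace_bad_channels(ep, integer(0))$data, ep$data)
  # a bad channel whose whole neighbourhood is bad is rejected
  expect_error(replace_bad_channels(ep, c("B2", nb)), "no good neighbour")
})

test_that("trial averaging is the arithmetic mean with CLT noise scaling", {
  g <- probe_geometry(3)
  one <- array(rnorm(3 * 30), c(1, 3, 30))
  same <- make_epochs(one[rep(1, 5), , , drop = FALSE], 100, 0.1, 0.2, g)
  expect_equal(average_epochs(same)$data, one[1, , ], tolerance = 1e-12)
  pair_arr <- array(0, c(2, 3, 30))
  pair_arr[1, , ] <- one[1, , ]
  pair_arr[2, , ] <- -one[1, , ]
  pair <- make_epochs(pair_arr, 100, 0.1, 0.2, g)
  expect_equal(max(abs(average_epochs(pair)$data)), 0)
  set.seed(3)
  noise <- make_epochs(array(rnorm(64 * 3 * 400, 0, 10), c(64, 3, 400)), 100, 1, 3, g)
  rms <- sqrt(mean(average_epochs(noise)$data^2))
  expect_equal(rms, 10 / 8, tolerance = 0.2)
})

test_that("the preprocessing chain records its provenance in order", {
  sc <- quiet_bc(n_trials = 2)
  rec <- simulate_grid_session(sc, fs = 4000)
  pp <- preprocess(rec)
  prov <- pp$avg$provenance
  nm <- names(prov)
  expect_true(all(c("downsampled_to", "epoch_window", "reference", "baseline",
                    "averaged_trials") %in% nm))
  expect_true(which(nm == "reference") < which(nm == "baseline"))
  expect_equal(prov$downsampled_to, 2000)
})
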