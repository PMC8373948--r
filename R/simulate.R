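# Synthetic-session generators. Both emit the same `sep_recording`
# container as real data would use, with the generator's ground truth
# retained in the metadata so downstream stages can be tested against it.

truncated_jitter <- function(n, sd) {
  if (sd == 0) return(rep(0, n))
  pmin(pmax(stats::rnorm(n, 0, sd), -3 * sd), 3 * sd)
}

draw_events <- function(config) {
  isi <- stats::runif(config$n_trials, config$isi_range[1], config$isi_range[2])
  cumsum(isi)
}

# add `amps %o% pulse` for one component occurrence into data (by reference
# semantics via returning the modified matrix)
add_pulse <- function(data, fs, amps, latency_ms, width_ms, event_s) {
  sigma_ms <- width_ms / GAUSS_HWHM
  t0 <- event_s + (latency_ms - 6 * sigma_ms) / 1000
  t1 <- event_s + (latency_ms + 6 * sigma_ms) / 1000
  i0 <- max(1L, floor(t0 * fs) + 1L)
  i1 <- min(ncol(data), ceiling(t1 * fs) + 1L)
  if (i1 < i0) return(data)
  idx <- i0:i1
  # pulse evaluated at exact sample times: sub-sample latency placement
  t_ms <- ((idx - 1) / fs - event_s) * 1000
  data[, idx] <- data[, idx] + amps %o% evoked_pulse(t_ms, latency_ms, width_ms)
  data
}

#' Simulate a surface-grid evoked-response session
#'
#' Generates a continuous multichannel recording in which each stimulus
#' adds, per channel, the sum over components of
#' `polarity * peak_amplitude * spatial_gain(channel) * pulse(t - latency - jitter)`,
#' with Gaussian (`exp(-d^2 / (2 sigma^2))`) or flat-top disk spatial
#' gains, plus additive zero-mean white noise. Stimulus times and the full
#' ground truth are stored in the recording. Fully reproducible from the
#' scenario's `rng_seed`.
#'
#' @param config A [scenario_config()].
#' @param geometry A [grid_geometry()].
#' @param fs Sampling rate, Hz (>= 2000 so downstream downsampling to
#'   2 kHz is well defined).
#' @return A [recording()].
#' @export
simulate_grid_session <- function(config, geometry = grid_geometry(), fs = 4000) {
  stopifnot(inherits(config, "scenario_config"), inherits(geometry, "grid_geometry"))
  if (fs < 2000) stop("fs must be >= 2000 Hz")
  ch <- geometry$channels
  hull <- c(range(ch$x), range(ch$y))
  for (cmp in config$components) {
    if (cmp$center[1] < hull[1] - geometry$pitch || cmp$center[1] > hull[2] + geometry$pitch ||
        cmp$center[2] < hull[3] - geometry$pitch || cmp$center[2] > hull[4] + geometry$pitch)
      warning(sprintf("component %s centre (%.0f, %.0f) um lies far outside the grid hull",
                      cmp$label, cmp$center[1], cmp$center[2]))
  }
  set.seed(config$rng_seed)
  events <- draw_events(config)
  n_samples <- ceiling((events[length(events)] + 2) * fs)
  data <- matrix(0, nrow = nrow(ch), ncol = n_samples)
  jit <- matrix(0, nrow = config$n_trials, ncol = length(config$components))
  for (j in seq_along(config$components))
    jit[, j] <- truncated_jitter(config$n_trials, config$latency_jitter_sd)
  for (j in seq_along(config$components)) {
    cmp <- config$components[[j]]
    if (cmp$peak_amplitude == 0) next
    amps <- cmp$polarity * cmp$peak_amplitude * spatial_gain(cmp, ch$x, ch$y)
    for (k in seq_len(config$n_trials))
      data <- add_pulse(data, fs, amps, cmp$latency + jit[k, j],
                        cmp$temporal_width, events[k])
  }
  if (config$noise_sd > 0)
    data <- data + matrix(stats::rnorm(length(data), 0, config$noise_sd),
                          nrow = nrow(data))
  recording(data, fs, geometry, events,
            ground_truth = list(kind = "grid",
                                components = config$components,
                                jitter = jit,
                                config = config),
            provenance = list(generator = "simulate_grid_session",
                              seed = config$rng_seed))
}

#' Simulate a laminar silicon-probe session
#'
#' Generates depth-resolved LFP plus multiunit spiking. The evoked LFP is
#' a depth dipole: a negative-going deflection at the configured sink site
#' with positive flanks (a Mexican-hat depth profile), following the
#' configured time course. Spikes are brief biphasic transients whose
#' expected count per trial peaks at the sink depth and whose times cluster
#' shortly after the stimulus; ground-truth sink depth and spike times are
#' kept in the recording metadata.
#'
#' @param config A [scenario_config()] with a `laminar` block (see
#'   [scenario_config()]); [bc_scenario()] provides one.
#' @param probe A [probe_geometry()] (>= 3 sites).
#' @param fs Sampling rate, Hz (>= 20000 so the spike band survives).
#' @return A [recording()].
#' @export
simulate_laminar_session <- function(config, probe = probe_geometry(), fs = 20000) {
  stopifnot(inherits(config, "scenario_config"), inherits(probe, "probe_geometry"))
  if (probe$n_sites < 3) stop("laminar simulation needs >= 3 sites")
  if (fs < 20000) stop("fs must be >= 20 kHz to retain the spike band")
  lam <- config$laminar
  if (is.null(lam)) stop("scenario config has no 'laminar' ground-truth block")
  defaults <- list(sink_site = 10L, sink_sigma_um = 100, lfp_amplitude = 200,
                   sink_latency = 42, sink_width = 6, spikes_per_trial = 8,
                   spike_time_sd = 8, spike_amplitude = 80)
  lam <- utils::modifyList(defaults, lam)
  if (config$ablated) {
    lam$lfp_amplitude <- 0
    lam$spikes_per_trial <- 0
  }
  depth <- probe$channels$depth
  sink_depth <- depth[lam$sink_site]
  u <- (depth - sink_depth) / lam$sink_sigma_um
  dipole <- -(1 - u^2) * exp(-u^2 / 2)  # -1 at the sink, positive flanks

  set.seed(config$rng_seed)
  events <- draw_events(config)
  n_samples <- ceiling((events[length(events)] + 2) * fs)
  data <- matrix(0, nrow = probe$n_sites, ncol = n_samples)
  jit <- truncated_jitter(config$n_trials, config$latency_jitter_sd)
  for (k in seq_len(config$n_trials))
    data <- add_pulse(data, fs, lam$lfp_amplitude * dipole,
                      lam$sink_latency + jit[k], lam$sink_width, events[k])

  # evoked multiunit spiking, rate peaked at the sink depth
  rate <- lam$spikes_per_trial * exp(-(depth - sink_depth)^2 / (2 * lam$sink_sigma_um^2))
  kern <- spike_kernel(fs) * lam$spike_amplitude
  spike_times <- vector("list", probe$n_sites)
  for (i in seq_len(probe$n_sites)) {
    times <- numeric(0)
    if (rate[i] > 0) {
      for (k in seq_len(config$n_trials)) {
        n_spk <- stats::rpois(1, rate[i])
        if (n_spk == 0) next
        tt <- events[k] + (lam$sink_latency + stats::rnorm(n_spk, 0, lam$spike_time_sd)) / 1000
        times <- c(times, tt[tt > events[k]])
      }
    }
    times <- sort(times)
    spike_times[[i]] <- times
    for (t0 in times) {
      i0 <- round(t0 * fs) + 1L
      idx <- i0:(i0 + length(kern) - 1L)
      keep <- idx <= n_samples
      data[i, idx[keep]] <- data[i, idx[keep]] + kern[keep]
    }
  }
  if (config$noise_sd > 0)
    data <- data + matrix(stats::rnorm(length(data), 0, config$noise_sd),
                          nrow = nrow(data))
  recording(data, fs, probe, events,
            ground_truth = list(kind = "laminar",
                                sink_site = lam$sink_site,
                                sink_depth = sink_depth,
                                sink_latency = lam$sink_latency,
                                spike_times = spike_times,
                                laminar = lam,
                                config = config),
            provenance = list(generator = "simulate_laminar_session",
                              seed = config$rng_seed))
}

# Brief biphasic extracellular spike waveform (unit trough), ~1.2 ms long.
spike_kernel <- function(fs) {
  t_ms <- seq(0, 1.2, by = 1000 / fs)
  -exp(-((t_ms - 0.3)^2) / (2 * 0.1^2)) +
    0.35 * exp(-((t_ms - 0.75)^2) / (2 * 0.2^2))
}
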