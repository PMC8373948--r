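# Shared fixtures, built in code.

# Small noise-free BC scenario for fast end-to-end runs.
quiet_bc <- function(n_trials = 3, rng_seed = 1L, ...) {
  bc_scenario(noise_sd = 0, latency_jitter_sd = 0, n_trials = n_trials,
              rng_seed = rng_seed, ...)
}

# Construct an epochs object directly from an array (trial x channel x time).
make_epochs <- function(data, fs, pre, post, geometry) {
  structure(
    list(data = data, fs = fs, window = c(pre = pre, post = post),
         event_times = numeric(dim(data)[1]), geometry = geometry,
         bad_channels = integer(0), ground_truth = NULL, provenance = list()),
    class = "sep_epochs"
  )
}

# Averaged-response object from a channel x time matrix.
make_avg <- function(data, fs, pre, post, geometry) {
  structure(
    list(data = data, n_trials_averaged = 1L, fs = fs,
         window = c(pre = pre, post = post), geometry = geometry,
         ground_truth = NULL, provenance = list()),
    class = "sep_avg"
  )
}

# Analytic disk region on the standard pixel grid, for overlap oracles.
make_disk_region <- function(cx, cy, radius, step, geometry = grid_geometry()) {
  ch <- geometry$channels
  xs <- seq(0, max(ch$x), by = step)
  ys <- seq(0, max(ch$y), by = step)
  mask <- outer((xs - cx)^2, (ys - cy)^2, "+") <= radius^2
  structure(
    list(mask = mask, area_mm2 = sum(mask) * step^2 / 1e6,
         peak = NULL, threshold = NA_real_, step = step,
         origin = c(x = 0, y = 0), truncated = FALSE),
    class = "half_width_region"
  )
}

# Brute-force rank-sum p-value by full enumeration of rank assignments.
brute_rank_sum_p <- function(a, b, alternative) {
  n_a <- length(a)
  r <- rank(c(a, b))
  obs <- sum(r[seq_len(n_a)])
  cmb <- utils::combn(length(r), n_a)
  W <- colSums(matrix(r[cmb], nrow = n_a))
  switch(alternative,
         less = mean(W <= obs),
         greater = mean(W >= obs),
         two.sided = min(1, 2 * min(mean(W <= obs), mean(W >= obs))))
}
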