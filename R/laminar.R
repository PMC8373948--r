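# Depth-resolved analysis of laminar probe recordings: multiunit spike
# detection, peristimulus time histograms and current source density.

#' Band-pass filter a recording into the multiunit band
#'
#' Zero-phase Butterworth band-pass (forward-backward), by default
#' 0.25-4 kHz, isolating multiunit spiking from the low-frequency LFP.
#'
#' @param rec A [recording()] with `fs > 2 * high`.
#' @param low,high Band edges in Hz.
#' @param order Butterworth order per pass (default 3).
#' @return The filtered [recording()].
#' @export
bandpass_mua <- function(rec, low = 250, high = 4000, order = 3) {
  stopifnot(inherits(rec, "sep_recording"), low > 0, high > low)
  if (rec$fs <= 2 * high)
    stop("sampling rate too low for the requested band (need fs > 2 * high)")
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  rec$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  rec$provenance <- c(rec$provenance, list(bandpass = c(low, high)))
  rec
}

#' Detect multiunit spikes by amplitude thresholding
#'
#' On each channel of a band-passed recording, a negative threshold is set
#' at `-k` times the robust (median-absolute-deviation based) SD. Each
#' sub-threshold excursion yields one spike at its trough time; troughs
#' within the refractory period of an accepted spike are suppressed.
#'
#' @param rec Band-passed [recording()].
#' @param k Threshold in robust SD units (default 4.5).
#' @param refractory Minimum inter-spike interval, ms (default 1).
#' @return A list of class `spike_trains`: per channel a list with `times`
#'   (seconds, strictly increasing), `channel` and `threshold_used` (uV).
#' @export
detect_spikes <- function(rec, k = 4.5, refractory = 1) {
  stopifnot(inherits(rec, "sep_recording"), k > 0, refractory > 0)
  refr_s <- refractory / 1000
  trains <- lapply(seq_len(nrow(rec$data)), function(i) {
    x <- rec$data[i, ]
    sd_rob <- stats::mad(x)
    thr <- -k * sd_rob
    times <- numeric(0)
    if (sd_rob > 0 && any(x < thr)) {
      below <- x < thr
      starts <- which(below & !c(FALSE, below[-length(below)]))
      ends <- which(below & !c(below[-1], FALSE))
      trough <- vapply(seq_along(starts), function(e) {
        seg <- starts[e]:ends[e]
        seg[which.min(x[seg])]
      }, integer(1))
      tt <- (trough - 1) / rec$fs
      kept <- tt[1]
      for (tm in tt[-1]) if (tm - kept[length(kept)] >= refr_s) kept <- c(kept, tm)
      times <- kept
    }
    list(times = times, channel = i, threshold_used = thr)
  })
  structure(trains, class = "spike_trains", fs = rec$fs)
}

#' @export
print.spike_trains <- function(x, ...) {
  n <- vapply(x, function(tr) length(tr$times), integer(1))
  cat(sprintf("spike trains on %d channels: %d spikes total (%.1f median/channel)\n",
              length(x), sum(n), stats::median(n)))
  invisible(x)
}

#' Peristimulus time histogram
#'
#' Bins spike times relative to each stimulus event with half-open bins
#' `[left, right)`, accumulating counts over trials, per channel.
#'
#' @param trains A [detect_spikes()] result (or any list of per-channel
#'   `list(times = ...)`).
#' @param events Stimulus times, seconds.
#' @param bin Bin width, ms (default 5).
#' @param window `c(pre, post)` window around the stimulus, ms
#'   (default `c(-50, 200)`).
#' @return An object of class `sep_psth`: `counts` (bin x channel integer
#'   matrix), `breaks` (ms), `bin`, `window`, `n_trials`.
#' @export
psth <- function(trains, events, bin = 5, window = c(-50, 200)) {
  stopifnot(bin > 0, length(window) == 2, window[1] < window[2])
  breaks <- seq(window[1], window[2], by = bin)
  if (breaks[length(breaks)] < window[2]) breaks <- c(breaks, breaks[length(breaks)] + bin)
  n_bins <- length(breaks) - 1
  counts <- matrix(0L, nrow = n_bins, ncol = length(trains))
  for (i in seq_along(trains)) {
    tt <- trains[[i]]$times
    if (length(tt) == 0 || length(events) == 0) next
    rel <- as.vector(outer(tt, events, "-")) * 1000
    rel <- rel[rel >= breaks[1] & rel < breaks[length(breaks)]]
    if (length(rel) == 0) next
    idx <- findInterval(rel, breaks, rightmost.closed = FALSE, left.open = FALSE)
    tab <- tabulate(idx, nbins = n_bins)
    counts[, i] <- counts[, i] + tab
  }
  structure(list(counts = counts, breaks = breaks, bin = bin,
                 window = window, n_trials = length(events)),
            class = "sep_psth")
}

#' @export
print.sep_psth <- function(x, ...) {
  cat(sprintf("PSTH: %d bins x %d channels, %g ms bins, window [%g, %g] ms, %d trials, %d spikes\n",
              nrow(x$counts), ncol(x$counts), x$bin, x$window[1], x$window[2],
              x$n_trials, sum(x$counts)))
  invisible(x)
}

#' Current source density of an averaged laminar LFP
#'
#' Second-spatial-difference CSD estimate:
#' `CSD_i(t) = -(phi_{i-1}(t) - 2 phi_i(t) + phi_{i+1}(t)) / h^2`
#' for interior sites (the two edge sites are dropped), with unit
#' conductivity so the output is in arbitrary units of uV/um^2. Sinks
#' (inward current) are negative. Any depth-constant offset of the LFP —
#' volume-conducted far-field signal — cancels exactly, and a linear
#' potential profile maps to zero CSD.
#'
#' @param avg Either a `sep_avg` on a [probe_geometry()] or a plain depth x
#'   time numeric matrix.
#' @param spacing Site spacing in um; taken from the geometry when `avg` is
#'   a `sep_avg`.
#' @return An object of class `sep_csd`: `values` (interior-depth x time),
#'   `depths` (um, when known), `spacing`.
#' @export
csd <- function(avg, spacing = NULL) {
  if (inherits(avg, "sep_avg")) {
    if (!inherits(avg$geometry, "probe_geometry"))
      stop("CSD needs a laminar probe recording")
    phi <- avg$data
    spacing <- avg$geometry$site_spacing
    depths <- avg$geometry$channels$depth
  } else {
    phi <- as.matrix(avg)
    if (is.null(spacing)) stop("supply the site spacing for a plain matrix")
    depths <- NULL
  }
  n <- nrow(phi)
  if (n < 3) stop("CSD needs at least 3 sites")
  stopifnot(spacing > 0)
  interior <- 2:(n - 1)
  vals <- -(phi[interior - 1, , drop = FALSE] - 2 * phi[interior, , drop = FALSE] +
              phi[interior + 1, , drop = FALSE]) / spacing^2
  structure(list(values = vals,
                 depths = if (!is.null(depths)) depths[interior] else NULL,
                 spacing = spacing),
            class = "sep_csd")
}

#' @export
print.sep_csd <- function(x, ...) {
  cat(sprintf("CSD map: %d interior depths x %d samples (%g um spacing); sinks negative\n",
              nrow(x$values), ncol(x$values), x$spacing))
  invisible(x)
}

#' Locate the dominant current sink
#'
#' @param csd_map A [csd()] result.
#' @return List with `depth_index` (index among interior sites), `depth`
#'   (um, if known), `time_index`, `value`.
#' @export
csd_sink <- function(csd_map) {
  stopifnot(inherits(csd_map, "sep_csd"))
  i <- which(csd_map$values == min(csd_map$values), arr.ind = TRUE)[1, ]
  list(depth_index = unname(i[1]),
       depth = if (!is.null(csd_map$depths)) csd_map$depths[i[1]] else NA_real_,
       time_index = unname(i[2]),
       value = csd_map$values[i[1], i[2]])
}
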