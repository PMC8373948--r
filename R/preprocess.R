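# Preprocessing: continuous recordings -> baseline-corrected, referenced,
# averaged epochs.

#' Detect stimulus onsets on a trigger trace by thresholding
#'
#' Returns the time of the first supra-threshold crossing of each event;
#' crossings within `refractory` seconds of a previously accepted onset are
#' suppressed (e.g. ringing of a mechanical tap detector).
#'
#' @param trigger_trace Numeric vector, the trigger/piezo channel.
#' @param threshold Detection threshold in trace units.
#' @param refractory Minimum separation between onsets, seconds (> 0).
#' @param fs Sampling rate of the trace, Hz.
#' @return Onset times in seconds from trace start.
#' @export
detect_stimulus_onsets <- function(trigger_trace, threshold, refractory, fs) {
  stopifnot(refractory > 0, fs > 0)
  if (length(trigger_trace) == 0) return(numeric(0))
  if (any(!is.finite(trigger_trace))) stop("trigger trace contains non-finite samples")
  above <- trigger_trace >= threshold
  cross <- which(above & !c(FALSE, above[-length(above)]))
  if (length(cross) == 0) return(numeric(0))
  times <- (cross - 1) / fs
  kept <- times[1]
  for (tm in times[-1]) if (tm - kept[length(kept)] >= refractory) kept <- c(kept, tm)
  kept
}

#' Downsample a recording with anti-alias filtering
#'
#' Applies a zero-phase low-pass filter at 0.4 x `target_fs` (4th-order
#' Butterworth, forward-backward) and decimates. The decimation factor must
#' be an integer; the DC level is preserved exactly.
#'
#' @param rec A [recording()].
#' @param target_fs Target sampling rate, Hz; must divide `rec$fs`.
#' @return The downsampled [recording()].
#' @export
downsample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "sep_recording"))
  if (target_fs > rec$fs) stop("target_fs exceeds the recording sampling rate")
  if (target_fs == rec$fs) return(rec)
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop("target_fs must divide the recording sampling rate (integer decimation)")
  q <- as.integer(round(q))
  bf <- signal::butter(4, 0.4 * target_fs / (rec$fs / 2), type = "low")
  filt <- t(apply(rec$data, 1, function(x) {
    m <- mean(x)  # filter around the mean so DC passes exactly
    m + signal::filtfilt(bf, x - m)
  }))
  rec$data <- filt[, seq(1, ncol(filt), by = q), drop = FALSE]
  rec$fs <- target_fs
  rec$provenance <- c(rec$provenance, list(downsampled_to = target_fs))
  rec
}

#' Split a recording into stimulus-aligned epochs
#'
#' Events lacking `pre` seconds of data before or `post` seconds after are
#' dropped (with a message reporting the count). In every retained trial the
#' sample at index `pre * fs + 1` corresponds to stimulus time.
#'
#' @param rec A [recording()].
#' @param events Stimulus times in seconds; defaults to the recording's own.
#' @param pre,post Window before/after the stimulus, seconds (> 0).
#' @return An object of class `sep_epochs` with fields `data`
#'   (trial x channel x time array), `fs`, `window`, `event_times`,
#'   `geometry`, `bad_channels`.
#' @export
epoch_recording <- function(rec, events = rec$events, pre = 0.5, post = 1.0) {
  stopifnot(inherits(rec, "sep_recording"), pre > 0, post > 0)
  n_pre <- round(pre * rec$fs)
  n_post <- round(post * rec$fs)
  n_len <- n_pre + n_post
  ns <- ncol(rec$data)
  i0 <- round(events * rec$fs) + 1L  # sample at stimulus time
  ok <- (i0 - n_pre >= 1L) & (i0 + n_post - 1L <= ns)
  if (sum(!ok) > 0)
    message(sprintf("dropping %d event(s) without a full [-%g, +%g] s window",
                    sum(!ok), pre, post))
  if (!any(ok)) stop("no events with a complete epoch window")
  i0 <- i0[ok]
  data <- array(0, dim = c(length(i0), nrow(rec$data), n_len))
  for (k in seq_along(i0))
    data[k, , ] <- rec$data[, (i0[k] - n_pre):(i0[k] + n_post - 1L)]
  structure(
    list(data = data, fs = rec$fs, window = c(pre = pre, post = post),
         event_times = events[ok], geometry = rec$geometry,
         bad_channels = integer(0), ground_truth = rec$ground_truth,
         provenance = c(rec$provenance, list(epoch_window = c(pre, post)))),
    class = "sep_epochs"
  )
}

#' @export
print.sep_epochs <- function(x, ...) {
  cat(sprintf("epochs: %d trials x %d channels x %d samples @ %g Hz (%g s pre, %g s post)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              x$window["pre"], x$window["post"]))
  invisible(x)
}

epoch_times_ms <- function(ep) {
  n_pre <- round(ep$window[["pre"]] * ep$fs)
  (seq_len(dim(ep$data)[3]) - 1 - n_pre) / ep$fs * 1000
}

#' Replace noisy channels by the mean of their neighbours
#'
#' Each declared bad channel is replaced, per trial and time sample, by the
#' arithmetic mean of its non-bad 4-neighbours on the grid (adjacent sites
#' on a probe); edge and corner channels use whichever neighbours exist.
#' Replacement values are computed from the original good channels only.
#'
#' @param ep A [epoch_recording()] result.
#' @param bad Channel indices or labels (e.g. `"C5"`) to replace.
#' @return The epochs with bad channels replaced and recorded in
#'   `$bad_channels`.
#' @export
replace_bad_channels <- function(ep, bad) {
  stopifnot(inherits(ep, "sep_epochs"))
  bad <- channel_index(bad, ep$geometry)
  if (length(bad) == 0) return(ep)
  for (b in bad) {
    nb <- setdiff(channel_neighbors(ep$geometry, b), bad)
    if (length(nb) == 0)
      stop(sprintf(paste("bad channel %s has no good neighbour to interpolate from;",
                         "declare fewer adjacent bad channels or drop it"),
                   ep$geometry$channels$label[b]))
    ep$data[, b, ] <- if (length(nb) == 1) ep$data[, nb, ]
                      else apply(ep$data[, nb, , drop = FALSE], c(1, 3), mean)
  }
  ep$bad_channels <- sort(unique(c(ep$bad_channels, bad)))
  ep$provenance <- c(ep$provenance, list(bad_channels_replaced = ep$bad_channels))
  ep
}

#' Flag noisy channels automatically (optional helper)
#'
#' Channels whose per-channel RMS (over all trials and samples) deviates
#' from the grid median by more than `z` robust z-score units are flagged.
#' Off by default in the pipeline; the standard workflow declares bad
#' channels explicitly.
#'
#' @param ep Epochs.
#' @param z Robust z-score threshold (default 5).
#' @return Integer channel indices.
#' @export
flag_bad_channels <- function(ep, z = 5) {
  stopifnot(inherits(ep, "sep_epochs"))
  rms <- sqrt(apply(ep$data^2, 2, mean))
  dev <- abs(rms - stats::median(rms)) / (stats::mad(rms) + 1e-12)
  which(dev > z)
}

#' Common-average reference
#'
#' Subtracts, at every trial and time sample, the mean across channels, so
#' that the across-channel mean is exactly zero afterwards. Bad channels
#' should be replaced first so they do not contaminate the reference.
#'
#' @param ep Epochs (>= 2 channels).
#' @return Referenced epochs.
#' @export
average_reference <- function(ep) {
  stopifnot(inherits(ep, "sep_epochs"))
  d <- dim(ep$data)
  if (d[2] < 2) stop("average reference needs more than one channel")
  m <- colMeans(aperm(ep$data, c(2, 1, 3)), dims = 1)  # trial x time
  ep$data <- ep$data - aperm(array(m, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  ep$provenance <- c(ep$provenance, list(reference = "common average"))
  ep
}

#' Baseline correction
#'
#' Subtracts from every trial and channel the mean of its pre-stimulus
#' window, so the pre-stimulus mean is exactly zero afterwards.
#'
#' @param ep Epochs with a non-empty pre-stimulus window.
#' @return Baseline-corrected epochs.
#' @export
baseline_correct <- function(ep) {
  stopifnot(inherits(ep, "sep_epochs"))
  n_pre <- round(ep$window[["pre"]] * ep$fs)
  if (n_pre < 1) stop("empty pre-stimulus window")
  d <- dim(ep$data)
  b <- rowMeans(ep$data[, , seq_len(n_pre), drop = FALSE], dims = 2)  # trial x channel
  ep$data <- ep$data - array(b, dim = d)
  ep$provenance <- c(ep$provenance, list(baseline = "pre-stimulus mean"))
  ep
}

#' Average epochs across trials
#'
#' @param ep Epochs (>= 1 trial).
#' @return An object of class `sep_avg`: fields `data` (channel x time
#'   matrix), `n_trials_averaged`, `fs`, `window`, `geometry`.
#' @export
average_epochs <- function(ep) {
  stopifnot(inherits(ep, "sep_epochs"), dim(ep$data)[1] >= 1)
  avg <- colMeans(ep$data, dims = 1)  # channel x time
  structure(
    list(data = avg, n_trials_averaged = dim(ep$data)[1], fs = ep$fs,
         window = ep$window, geometry = ep$geometry,
         ground_truth = ep$ground_truth,
         provenance = c(ep$provenance, list(averaged_trials = dim(ep$data)[1]))),
    class = "sep_avg"
  )
}

#' @export
print.sep_avg <- function(x, ...) {
  cat(sprintf("averaged response: %d channels x %d samples @ %g Hz (mean of %d trials)\n",
              nrow(x$data), ncol(x$data), x$fs, x$n_trials_averaged))
  invisible(x)
}

#' Standard preprocessing chain
#'
#' Runs the fixed pipeline order: downsample, epoch, replace bad channels,
#' common-average reference, baseline correction, trial averaging. Each
#' step records itself in the output provenance.
#'
#' @param rec A [recording()].
#' @param target_fs Downsampling target, Hz (default 2000).
#' @param pre,post Epoch window, seconds (defaults 0.5 and 1.0).
#' @param bad_channels Channels to replace (indices or labels).
#' @return A list with `epochs` (`sep_epochs`) and `avg` (`sep_avg`).
#' @export
preprocess <- function(rec, target_fs = 2000, pre = 0.5, post = 1.0,
                       bad_channels = integer(0)) {
  rec <- downsample_recording(rec, target_fs)
  ep <- epoch_recording(rec, pre = pre, post = post)
  ep <- replace_bad_channels(ep, bad_channels)
  ep <- average_reference(ep)
  ep <- baseline_correct(ep)
  list(epochs = ep, avg = average_epochs(ep))
}
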