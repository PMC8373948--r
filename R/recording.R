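# The continuous-recording container shared by real and synthetic data:
# a channels x samples signal matrix plus geometry, sampling rate, stimulus
# event times and (for synthetic sessions) a ground-truth block.

#' Construct a continuous multichannel recording
#'
#' @param data Numeric matrix, channels x samples, microvolts.
#' @param fs Sampling rate, Hz.
#' @param geometry A [grid_geometry()] or [probe_geometry()] whose channel
#'   count matches `nrow(data)`.
#' @param events Stimulus onset times in seconds from recording start.
#' @param ground_truth Optional list of generator ground truth.
#' @param provenance Optional list describing how the recording was made.
#' @return An object of class `sep_recording`.
#' @export
recording <- function(data, fs, geometry, events = numeric(0),
                      ground_truth = NULL, provenance = list()) {
  stopifnot(is.matrix(data), fs > 0, nrow(data) == n_channels(geometry))
  structure(
    list(data = data, fs = fs, geometry = geometry,
         events = as.numeric(events), ground_truth = ground_truth,
         provenance = provenance),
    class = "sep_recording"
  )
}

#' @export
print.sep_recording <- function(x, ...) {
  cat(sprintf("continuous recording: %d channels x %d samples @ %g Hz (%.1f s), %d stimulus events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              length(x$events)))
  print(x$geometry)
  invisible(x)
}

## ---- raw float32 + JSON sidecar container ----------------------------------

# Strip S3 classes and NULL fields so metadata serializes as plain JSON,
# and collapse unnamed lists of scalars to atomic vectors so that
# write(read(x)) reproduces the file byte-for-byte.
sanitize_meta <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x <- x[!vapply(x, is.null, TRUE)]
    x <- lapply(x, sanitize_meta)
    scalar <- vapply(x, function(e) is.atomic(e) && length(e) == 1, TRUE)
    if (length(x) > 0 && is.null(names(x)) && all(scalar)) unlist(x) else x
  } else x
}

geometry_to_list <- function(g) {
  if (inherits(g, "grid_geometry")) {
    list(type = "grid", n_rows = g$n_rows, n_cols = g$n_cols, pitch = g$pitch)
  } else {
    list(type = "probe", n_sites = g$n_sites, site_spacing = g$site_spacing,
         insertion_depth = g$insertion_depth)
  }
}

geometry_from_list <- function(l) {
  if (l$type == "grid") grid_geometry(l$n_rows, l$n_cols, l$pitch)
  else probe_geometry(l$n_sites, l$site_spacing, l$insertion_depth)
}

#' Write a recording to an on-disk container
#'
#' The container is a directory holding `signal.f32` — raw little-endian
#' 32-bit float samples in channel-major frames (all channels of sample 1,
#' then all channels of sample 2, ...) — and `metadata.json` with the
#' sampling rate, channel ids, geometry, event times and any ground-truth
#' block. Samples are quantized to float32 on write; writing a container
#' read back from disk reproduces the files bit-exactly.
#'
#' @param rec A [recording()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "sep_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(path, "signal.f32"), "wb")
  on.exit(close(con))
  # column-major write of the channels x samples matrix = channel-major frames
  writeBin(as.numeric(rec$data), con, size = 4L, endian = "little")
  meta <- list(
    format = "sepmap-recording-v1",
    fs = rec$fs,
    n_channels = nrow(rec$data),
    n_samples = ncol(rec$data),
    channel_ids = rec$geometry$channels$label,
    geometry = geometry_to_list(rec$geometry),
    events = rec$events,
    ground_truth = sanitize_meta(rec$ground_truth),
    provenance = sanitize_meta(rec$provenance)
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a recording container written by [write_recording()]
#'
#' @param path Container directory.
#' @return A [recording()].
#' @export
read_recording <- function(path) {
  # keep the nested list structure untouched so write(read(x)) reproduces
  # the metadata file bit-exactly
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = FALSE)
  if (!identical(meta$format, "sepmap-recording-v1"))
    stop("not a sepmap recording container: ", path)
  n <- meta$n_channels * meta$n_samples
  con <- file(file.path(path, "signal.f32"), "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = n, size = 4L, endian = "little")
  if (length(x) != n) stop("truncated signal file in ", path)
  recording(matrix(x, nrow = meta$n_channels),
            fs = meta$fs,
            geometry = geometry_from_list(meta$geometry),
            events = as.numeric(unlist(meta$events)),
            ground_truth = meta$ground_truth,
            provenance = meta$provenance)
}

## ---- scenario configuration files ------------------------------------------

#' Write a scenario configuration to a YAML file
#'
#' The file mirrors [scenario_config()] field-for-field, so configurations
#' are round-trippable and human-editable.
#'
#' @param config A [scenario_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  x <- unclass(config)
  x$components <- lapply(x$components, function(cmp) {
    cmp[!vapply(cmp, is.null, TRUE)]
  })
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read a scenario configuration from YAML
#'
#' @param path File written by [write_scenario_config()] (or hand-authored
#'   with the same fields).
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  comps <- lapply(x$components, function(cmp) {
    component_spec(label = cmp$label, latency = cmp$latency,
                   temporal_width = cmp$temporal_width,
                   peak_amplitude = cmp$peak_amplitude,
                   center = unlist(cmp$center),
                   footprint_sigma = cmp$footprint_sigma,
                   footprint_radius = cmp$footprint_radius,
                   polarity = cmp$polarity)
  })
  scenario_config(age = x$age, modality = x$modality, components = comps,
                  n_trials = x$n_trials, isi_range = unlist(x$isi_range),
                  noise_sd = x$noise_sd,
                  latency_jitter_sd = x$latency_jitter_sd,
                  ablated = isTRUE(x$ablated), rng_seed = x$rng_seed,
                  laminar = x$laminar)
}
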