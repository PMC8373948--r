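# Ground-truth parameterization of synthetic evoked sessions: component
# descriptions, developmental latency model, and footprint calibration.

GAUSS_HWHM <- sqrt(2 * log(2))  # half-width at half-maximum of exp(-u^2/2), in SD units

# Smooth unimodal evoked pulse: unit-peak Gaussian in time.
# `width` is the half-duration at half maximum (ms), so sigma = width / sqrt(2 ln 2).
evoked_pulse <- function(t_ms, latency_ms, width_ms) {
  s <- width_ms / GAUSS_HWHM
  exp(-((t_ms - latency_ms)^2) / (2 * s^2))
}

# Closed-form mean of the unit pulse over [latency - hw, latency + hw] (hw in ms).
pulse_window_mean <- function(width_ms, half_window_ms) {
  if (half_window_ms == 0) return(1)
  s <- width_ms / GAUSS_HWHM
  s * sqrt(2 * pi) * (2 * stats::pnorm(half_window_ms / s) - 1) / (2 * half_window_ms)
}

#' Specification of one evoked component
#'
#' Describes the ground truth of a single surface component: an early
#' positive (P) or delayed negative (N) deflection with a smooth unimodal
#' time course and an isotropic spatial footprint on the cortical sheet,
#' either Gaussian (`footprint_sigma`) or a flat-top disk
#' (`footprint_radius`). Exactly one of the two footprint parameters must
#' be given.
#'
#' @param label `"P"` or `"N"`.
#' @param latency Peak latency in ms post-stimulus (> 0).
#' @param temporal_width Half-duration of the pulse at half maximum, ms.
#' @param peak_amplitude Peak amplitude magnitude in microvolts (> 0); the
#'   sign is carried by `polarity`.
#' @param center Planar coordinates `c(x, y)` of the footprint centre, um,
#'   in the caudal/medial frame of [grid_geometry()].
#' @param footprint_sigma Gaussian spatial decay scale, um.
#' @param footprint_radius Disk radius, um (alternative to `footprint_sigma`).
#' @param polarity `+1` or `-1`; defaults to `+1` for P and `-1` for N.
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(label, latency, temporal_width, peak_amplitude,
                           center, footprint_sigma = NULL,
                           footprint_radius = NULL,
                           polarity = if (label == "P") 1 else -1) {
  stopifnot(label %in% c("P", "N"), latency > 0, temporal_width > 0,
            peak_amplitude > 0, polarity %in% c(-1, 1),
            length(center) == 2,
            xor(is.null(footprint_sigma), is.null(footprint_radius)))
  if (!is.null(footprint_sigma)) stopifnot(footprint_sigma > 0)
  if (!is.null(footprint_radius)) stopifnot(footprint_radius > 0)
  structure(
    list(label = label, polarity = polarity, latency = latency,
         temporal_width = temporal_width, peak_amplitude = peak_amplitude,
         center = as.numeric(center), footprint_sigma = footprint_sigma,
         footprint_radius = footprint_radius),
    class = "component_spec"
  )
}

# Spatial gain of a component at planar positions (x, y): 1 at the centre.
spatial_gain <- function(comp, x, y) {
  d2 <- (x - comp$center[1])^2 + (y - comp$center[2])^2
  if (!is.null(comp$footprint_sigma)) {
    exp(-d2 / (2 * comp$footprint_sigma^2))
  } else {
    as.numeric(sqrt(d2) <= comp$footprint_radius)
  }
}

#' Exponential developmental latency model
#'
#' Evoked-response latencies shorten over early postnatal development and
#' are modelled as an exponential decay towards an asymptote:
#' `latency(age) = a * exp(-b * (age - reference_age)) + c`.
#'
#' @param a Amplitude of the decaying part, ms.
#' @param b Decay rate per postnatal day (>= 0).
#' @param c Asymptotic (mature) latency, ms (> 0).
#' @param reference_age Youngest modelled age, postnatal day.
#' @return An object of class `age_latency_model`.
#' @seealso [latency_at_age()], [fit_exponential_trend()]
#' @export
age_latency_model <- function(a, b, c, reference_age = 8) {
  stopifnot(c > 0, b >= 0, a + c > 0)
  structure(list(a = a, b = b, c = c, reference_age = reference_age),
            class = "age_latency_model")
}

#' Evaluate a developmental latency model at given ages
#'
#' @param model An [age_latency_model()].
#' @param age Postnatal day(s), each `>= reference_age`.
#' @return Latency in ms for each age.
#' @export
latency_at_age <- function(model, age) {
  stopifnot(inherits(model, "age_latency_model"), all(age >= model$reference_age))
  model$a * exp(-model$b * (age - model$reference_age)) + model$c
}

#' Scenario configuration for a synthetic session
#'
#' Bundles everything the generator needs: age and stimulation modality,
#' the ground-truth components, trial structure and noise levels. If
#' `ablated = TRUE` (emulating bilateral cochlear ablation) all component
#' amplitudes are forced to zero before synthesis, so stimuli evoke no
#' cortical response.
#'
#' @param age Postnatal day.
#' @param modality One of `"BC"`, `"AC"`, `"ASW"`, `"iCo"`, `"IC"`.
#' @param components List of [component_spec()] objects.
#' @param n_trials Number of stimuli (>= 1).
#' @param isi_range Inter-stimulus interval range in seconds, default 3-5 s.
#' @param noise_sd Additive white-noise SD, microvolts (>= 0).
#' @param latency_jitter_sd Trial-to-trial latency jitter SD, ms
#'   (Gaussian, truncated at 3 SD so component order is preserved).
#' @param ablated Logical; zero out all evoked amplitudes.
#' @param rng_seed Integer seed making the session reproducible.
#' @param laminar Optional list of laminar ground-truth parameters used by
#'   [simulate_laminar_session()]: `sink_site`, `sink_sigma_um`,
#'   `lfp_amplitude` (uV), `sink_latency` (ms; defaults to the P latency),
#'   `sink_width` (ms), `spikes_per_trial` (expected count at the sink
#'   site), `spike_time_sd` (ms), `spike_amplitude` (uV).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(age = 8, modality = "BC", components,
                            n_trials = 44L, isi_range = c(3, 5),
                            noise_sd = 10, latency_jitter_sd = 1,
                            ablated = FALSE, rng_seed = 1L,
                            laminar = NULL) {
  stopifnot(n_trials >= 1, noise_sd >= 0, latency_jitter_sd >= 0,
            length(isi_range) == 2, all(isi_range > 0),
            isi_range[1] <= isi_range[2],
            modality %in% c("BC", "AC", "ASW", "iCo", "IC"))
  if (!is.list(components) || !all(vapply(components, inherits, TRUE, "component_spec")))
    stop("'components' must be a list of component_spec objects")
  if (ablated)
    components <- lapply(components, function(cmp) { cmp$peak_amplitude <- 0; cmp })
  structure(
    list(age = age, modality = modality, components = components,
         n_trials = as.integer(n_trials), isi_range = isi_range,
         noise_sd = noise_sd, latency_jitter_sd = latency_jitter_sd,
         ablated = ablated, rng_seed = as.integer(rng_seed),
         laminar = laminar),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario: %s, P%d, %d trials, noise %g uV, jitter %g ms%s\n",
              x$modality, x$age, x$n_trials, x$noise_sd, x$latency_jitter_sd,
              if (x$ablated) " [ablated]" else ""))
  for (cmp in x$components) {
    fp <- if (!is.null(cmp$footprint_sigma))
      sprintf("Gaussian sigma %.0f um", cmp$footprint_sigma)
    else sprintf("disk radius %.0f um", cmp$footprint_radius)
    cat(sprintf("  %s: %g ms, %+g uV, centre (%.0f, %.0f) um, %s\n",
                cmp$label, cmp$latency, cmp$polarity * cmp$peak_amplitude,
                cmp$center[1], cmp$center[2], fp))
  }
  invisible(x)
}

## ---- footprint calibration -------------------------------------------------

#' Area of the intersection of two disks (circle lens)
#'
#' Closed-form area of the lens formed by two disks of radii `r1`, `r2`
#' whose centres are `d` apart. Used as the analytic oracle for the
#' pixel-counting overlap measurement and to design overlap scenarios.
#'
#' @param r1,r2 Disk radii (same units).
#' @param d Centre distance.
#' @return Intersection area in squared input units.
#' @export
lens_area <- function(r1, r2, d) {
  stopifnot(r1 > 0, r2 > 0, d >= 0)
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1)) +
    r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2)) -
    0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
}

# Mean Gaussian spatial gain over the grid electrodes: the across-channel
# spatial mean removed by common-average referencing.
mean_grid_gain <- function(sigma, center, geometry) {
  ch <- geometry$channels
  mean(exp(-((ch$x - center[1])^2 + (ch$y - center[2])^2) / (2 * sigma^2)))
}

#' Half-maximum region radius measured after common-average referencing
#'
#' Common-average referencing subtracts, at each time point, the
#' across-channel mean of the field. For a Gaussian footprint with unit
#' peak this replaces the gain `g` by `g - m`, where `m` is the mean gain
#' over the electrodes, so the half-maximum region becomes
#' `{g >= (1 + m) / 2}` with radius `sigma * sqrt(2 * log(2 / (1 + m)))`
#' rather than the unreferenced `sigma * sqrt(2 * log(2))`.
#'
#' @param sigma Gaussian footprint scale, um.
#' @param center Footprint centre `c(x, y)`, um.
#' @param geometry The [grid_geometry()] the reference is computed over.
#' @return Radius of the measured half-maximum disk, um.
#' @seealso [sigma_for_halfwidth_area()]
#' @export
referenced_halfwidth_radius <- function(sigma, center, geometry) {
  m <- mean_grid_gain(sigma, center, geometry)
  if (m >= 1) return(0)
  sigma * sqrt(2 * log(2 / (1 + m)))
}

#' Gaussian footprint scale realizing a target half-width area
#'
#' Solves for the footprint `sigma` such that the half-maximum region
#' *measured by the full pipeline* (which includes common-average
#' referencing, see [referenced_halfwidth_radius()]) has the target area.
#' With `referenced = FALSE` the unreferenced closed form
#' `sigma = sqrt(A / (2 * pi * log(2)))` is returned instead.
#'
#' @param area_mm2 Target half-width area, mm^2.
#' @param center Footprint centre, um.
#' @param geometry [grid_geometry()] used for the reference mean.
#' @param referenced Account for common-average referencing (default TRUE).
#' @return Footprint sigma in um.
#' @export
sigma_for_halfwidth_area <- function(area_mm2, center = NULL, geometry = NULL,
                                     referenced = TRUE) {
  stopifnot(area_mm2 > 0)
  if (!referenced) return(sqrt(area_mm2 * 1e6 / (2 * pi * log(2))))
  stopifnot(!is.null(center), !is.null(geometry))
  target_r <- sqrt(area_mm2 * 1e6 / pi)
  sigma_for_referenced_radius(target_r, center, geometry)
}

# sigma such that the referenced half-maximum disk has radius target_r (um)
sigma_for_referenced_radius <- function(target_r, center, geometry) {
  f <- function(s) referenced_halfwidth_radius(s, center, geometry) - target_r
  stats::uniroot(f, lower = target_r / GAUSS_HWHM, upper = 20 * target_r,
                 tol = 1e-6)$root
}

# Solve the radius of disk A so that lens(rA, rB, d) equals `frac` of disk A
# (of = "A") or of disk B (of = "B").
solve_overlap_radius <- function(r_other, d, frac, of = c("A", "B")) {
  of <- match.arg(of)
  f <- function(rA) {
    I <- lens_area(rA, r_other, d)
    if (of == "A") I / (pi * rA^2) - frac else I / (pi * r_other^2) - frac
  }
  stats::uniroot(f, lower = 1, upper = 4 * (r_other + d), tol = 1e-8)$root
}

## ---- default study scenarios ----------------------------------------------

# Default developmental latency models: chosen so that the P and N latencies
# at P8 are 42 ms and 62 ms (the example animal) decaying towards short
# near-adult values by P15-16.
default_latency_models <- function() {
  list(P = age_latency_model(a = 27, b = 0.3, c = 15, reference_age = 8),
       N = age_latency_model(a = 37, b = 0.3, c = 25, reference_age = 8))
}

#' Default bone-conduction scenario keyed to the reported group geometry
#'
#' Builds the canonical bone-conducted (BC) stimulation scenario used
#' throughout the package: a biphasic response whose ground-truth spatial
#' layout mirrors the reported group means — the N peak displaced
#' `pn_distance` um from the P peak at `pn_angle` degrees (0 deg = caudal,
#' negative = lateral), an N half-width area of `n_area_mm2`, and a P
#' half-width region sized so the P/N intersection constitutes
#' `overlap_frac` of the half-width area named by `overlap_of`. Footprint
#' scales are calibrated for measurement through the full pipeline
#' (see [sigma_for_halfwidth_area()]).
#'
#' @param age Postnatal day (default 8; latencies follow the built-in
#'   developmental model, 42/62 ms at P8).
#' @param geometry Grid geometry, default [grid_geometry()].
#' @param pn_distance P-to-N peak distance, um.
#' @param pn_angle P-to-N angle, degrees (0 = caudal, negative = lateral).
#' @param n_area_mm2 N half-width area, mm^2.
#' @param overlap_frac Designed intersection fraction.
#' @param overlap_of `"P"` or `"N"`: which half-width area the fraction
#'   refers to.
#' @param p_amplitude,n_amplitude Peak amplitude magnitudes, uV.
#' @param noise_sd,latency_jitter_sd,n_trials,rng_seed,ablated Passed to
#'   [scenario_config()].
#' @return A [scenario_config()].
#' @export
bc_scenario <- function(age = 8, geometry = grid_geometry(),
                        pn_distance = 339, pn_angle = -35,
                        n_area_mm2 = 1.11,
                        overlap_frac = 0.76, overlap_of = c("P", "N"),
                        p_amplitude = 60, n_amplitude = 120,
                        noise_sd = 10, latency_jitter_sd = 1,
                        n_trials = 44L, rng_seed = 1L, ablated = FALSE) {
  overlap_of <- match.arg(overlap_of)
  models <- default_latency_models()
  lat_p <- latency_at_age(models$P, age)
  lat_n <- latency_at_age(models$N, age)
  # P centred on the electrode nearest the grid centre, shifted rostrally
  # if needed so both designed half-width disks fit inside the hull
  # (a truncated region would only bound the area from below)
  ch <- geometry$channels
  cx <- mean(range(ch$x)); cy <- mean(range(ch$y))
  i <- which.min((ch$x - cx)^2 + (ch$y - cy)^2)
  p_center <- c(ch$x[i], ch$y[i])
  th <- pn_angle * pi / 180
  r_n <- sqrt(n_area_mm2 * 1e6 / pi)
  r_p <- solve_overlap_radius(r_n, pn_distance, overlap_frac,
                              of = if (overlap_of == "P") "A" else "B")
  fits <- function(centre, r) {
    centre[1] - r >= min(ch$x) && centre[1] + r <= max(ch$x) &&
      centre[2] - r >= min(ch$y) && centre[2] + r <= max(ch$y)
  }
  repeat {
    n_center <- p_center + pn_distance * c(cos(th), sin(th))
    if ((fits(p_center, r_p) && fits(n_center, r_n)) ||
        p_center[1] - geometry$pitch < min(ch$x)) break
    p_center[1] <- p_center[1] - geometry$pitch
  }
  comps <- list(
    component_spec("P", latency = lat_p, temporal_width = 5,
                   peak_amplitude = p_amplitude, center = p_center,
                   footprint_sigma = sigma_for_referenced_radius(r_p, p_center, geometry)),
    component_spec("N", latency = lat_n, temporal_width = 7,
                   peak_amplitude = n_amplitude, center = n_center,
                   footprint_sigma = sigma_for_referenced_radius(r_n, n_center, geometry))
  )
  scenario_config(age = age, modality = "BC", components = comps,
                  n_trials = n_trials, noise_sd = noise_sd,
                  latency_jitter_sd = latency_jitter_sd,
                  ablated = ablated, rng_seed = rng_seed,
                  laminar = list(sink_site = 10L, sink_sigma_um = 100,
                                 lfp_amplitude = 200, sink_latency = lat_p,
                                 sink_width = 6, spikes_per_trial = 8,
                                 spike_time_sd = 8, spike_amplitude = 80))
}

#' Air-conducted shock-wave (ASW) scenario co-localized with BC
#'
#' Scenario emulating high-intensity air-conducted shock-wave stimulation:
#' the same biphasic response topography as [bc_scenario()] but with the P
#' centre displaced `p_offset` um from the BC P centre (at `offset_angle`
#' degrees), the N peak shifted from the ASW P by `pn_distance` at the
#' usual caudolateral angle, and a slight extra latency. By default the
#' footprint scales mirror the BC scenario: evoked footprints narrower
#' than the electrode pitch are marginally sampled by the grid and cannot
#' be localized to map-pixel accuracy, so mirroring BC keeps the scenario
#' within the grid's resolving power. Explicit half-width-area targets can
#' be requested via `p_area_mm2` / `n_area_mm2` instead.
#'
#' @param age Postnatal day.
#' @param geometry Grid geometry.
#' @param p_offset Distance between ASW and BC P centres, um.
#' @param offset_angle Direction of the offset, degrees (0 = caudal,
#'   positive = medial).
#' @param pn_distance ASW P-to-N peak distance, um.
#' @param p_area_mm2,n_area_mm2 Optional half-width-area targets, mm^2
#'   (default `NULL`: use the BC footprint scales).
#' @param extra_latency Added latency relative to BC, ms.
#' @param noise_sd,latency_jitter_sd,n_trials,rng_seed Passed through.
#' @return A [scenario_config()].
#' @export
asw_scenario <- function(age = 8, geometry = grid_geometry(),
                         p_offset = 184, offset_angle = 25,
                         pn_distance = 297,
                         p_area_mm2 = NULL, n_area_mm2 = NULL,
                         extra_latency = 6.7,
                         noise_sd = 10, latency_jitter_sd = 1,
                         n_trials = 44L, rng_seed = 2L) {
  base <- bc_scenario(age = age, geometry = geometry, noise_sd = noise_sd,
                      latency_jitter_sd = latency_jitter_sd,
                      n_trials = n_trials, rng_seed = rng_seed)
  p_bc <- base$components[[1]]
  n_bc <- base$components[[2]]
  th <- offset_angle * pi / 180
  p_center <- p_bc$center + p_offset * c(cos(th), sin(th))
  n_center <- p_center + pn_distance * c(cos(-35 * pi / 180), sin(-35 * pi / 180))
  sig_p <- if (is.null(p_area_mm2)) p_bc$footprint_sigma
           else sigma_for_halfwidth_area(p_area_mm2, p_center, geometry)
  sig_n <- if (is.null(n_area_mm2)) n_bc$footprint_sigma
           else sigma_for_halfwidth_area(n_area_mm2, n_center, geometry)
  comps <- list(
    component_spec("P", latency = p_bc$latency + extra_latency,
                   temporal_width = 5, peak_amplitude = 50, center = p_center,
                   footprint_sigma = sig_p),
    component_spec("N", latency = n_bc$latency + extra_latency,
                   temporal_width = 7, peak_amplitude = 100, center = n_center,
                   footprint_sigma = sig_n)
  )
  scenario_config(age = age, modality = "ASW", components = comps,
                  n_trials = n_trials, noise_sd = noise_sd,
                  latency_jitter_sd = latency_jitter_sd, rng_seed = rng_seed)
}
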