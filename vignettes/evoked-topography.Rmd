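---
title: "Topographic analysis of developing-cortex evoked responses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topographic analysis of developing-cortex evoked responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepmap)
```

## The problem

In neonatal rodents, sensory stimulation evokes a stereotyped biphasic
surface response in cortex: an early positive deflection (P) followed by a
delayed negative one (N), the precursors of the adult P1/N1 complex.
Recorded with a dense epidural micro-ECoG grid (here 6 × 10 electrodes at
400 µm pitch) these components form spatial amplitude maps whose peak
positions, mutual displacement and half-maximum footprints quantify how a
developing cortical area represents a stimulus. A simultaneously inserted
laminar probe (16 sites, 50 µm spacing) resolves the same response in
depth: the current sink marking thalamocortical input and the multiunit
spiking it drives.

`sepmap` implements this analysis chain as a reusable, tested pipeline:
session simulation with known ground truth, preprocessing, component-peak
extraction, spline-interpolated topographic maps, half-maximum area and
overlap quantification, polar displacement statistics, circular and
developmental statistics, and depth-resolved (PSTH/CSD) analysis.

## The synthetic generator and what it emulates

No public recordings accompany this analysis style, so the package ships a
generator whose output uses the same container as real data would
(`recording()`: a channels × samples matrix, geometry, stimulus events).
Each stimulus adds, per channel,

$$ \sum_{k \in \{P, N\}} s_k\, A_k\, g_k(\mathbf{x})\,
   \exp\!\left(-\frac{(t - \tau_k - \epsilon)^2}{2\sigma_{t,k}^2}\right), $$

with polarity $s_k = \pm 1$, peak amplitude $A_k$ (µV), an isotropic
spatial gain $g_k(\mathbf{x}) = \exp(-d^2 / 2\sigma_k^2)$ (or a flat-top
disk), latency $\tau_k$ (ms) with per-trial Gaussian jitter $\epsilon$
truncated at 3 SD (so P always precedes N), plus white Gaussian noise.
Pulses are evaluated at exact sample times, so latencies live on a
continuous axis, not on the sample grid — required for sub-millisecond
latency recovery at 2 kHz. A Gaussian-in-time pulse was chosen because the
waveform is observed to be smooth and unimodal but is not otherwise
parameterized by the data; its half-duration at half-maximum is the
`temporal_width` parameter (defaults 5 ms for P, 7 ms for N, preserving
the shorter-P/longer-N ordering; widths were kept narrow enough that the
two components do not contaminate each other's ±1 ms measurement windows
20 ms apart).

Default study conditions follow the recording protocol and published group
geometry: 44 stimuli at 3–5 s inter-stimulus intervals; P latency 42 ms
and N latency 62 ms at postnatal day 8, decaying with age as
$a e^{-b(\text{age} - 8)} + c$; the N peak displaced 339 µm from the P
peak at −35° (0° = caudal, negative = lateral); an N half-width area of
1.11 mm²; and a P footprint sized so that the P∩N intersection occupies a
designed fraction (0.76 of the P area, or in an alternative configuration
0.48 of the N area). Evoked amplitudes are not published in µV, so the
defaults (P +60, N −120 µV; noise SD 10 µV) only fix a realistic
signal-to-noise scale; every recovered spatial quantity is amplitude-free.
Ablation scenarios (`ablated = TRUE`) zero all evoked amplitudes,
emulating bilateral cochlear ablation.

The laminar generator realizes the depth profile as a Mexican-hat dipole —
a negative-going deflection at the sink site (default site 10, ≈ L4 for
the default insertion) with positive flanks — and emits brief biphasic
spike transients whose per-trial expected count peaks at the sink depth
shortly after the stimulus.

What the generator does *not* emulate: anisotropic or non-Gaussian
footprints (real N components spread caudolaterally), structured (1/f,
line) noise, trial-to-trial amplitude variability, and electrode-level
artifacts. Passing recovery tests therefore demonstrate correctness of the
measurement chain under idealized fields, not robustness to every property
of in-vivo data.

## Preprocessing

The fixed order is: anti-aliased downsampling to 2 kHz (zero-phase 4th
order Butterworth at 0.4 × target rate, so no latency bias; DC preserved
exactly) → epoching into 1.5 s windows (0.5 s pre-, 1.0 s post-stimulus) →
bad-channel replacement → common-average reference → baseline correction →
trial averaging. Two points were genuinely open and are fixed here by
argument rather than by the protocol description:

* **Bad channels before referencing.** A noisy channel left in place would
  contaminate the common average of all channels; replacement (mean of the
  non-bad 4-neighbours, edge channels using whichever neighbours exist)
  therefore precedes referencing.
* **Reference before baseline.** Both operations are linear projections and
  commute in exact arithmetic; the order is fixed (reference, then
  baseline) and recorded in the output provenance so reruns are
  reproducible.

Declared bad channels are the supported workflow; an RMS-z-score flagger
(`flag_bad_channels()`) exists but is off by default because no objective
criterion is published.

## Topographic measurement

Component peaks are the extrema of the averaged response over channels
within search windows (defaults: P in 10–80 ms, N from the P latency to
300 ms; the windows are configurable per age because the original windows
are unpublished). Latencies are refined by a 3-point parabolic fit —
at 2 kHz the 0.5 ms sample grid cannot otherwise express sub-millisecond
latency differences. Per-channel amplitudes are averaged in a ±1 ms window
around the component latency, interpolated over the grid hull by a
tensor-product natural cubic spline (exact at electrode positions), and
the map peak is the pixel argmax/argmin. The half-width region is the
4-connected set of pixels at or beyond half the signed peak amplitude that
contains the peak; connectivity prevents disconnected satellite lobes from
inflating areas, and regions touching the map border are flagged as
truncated (their area is only a lower bound). Displacements between peaks
are reported in polar form, $r = \sqrt{x^2+y^2}$,
$\theta = \operatorname{atan2}(y, x)$, with 0° caudal and negative angles
lateral.

Numerical choices:

* **Pixel step 10 µm** by default. The published maps used 1 µm, which is
  supported (`step = 1`) but ~100× more pixels; peak positions at 10 µm and
  1 µm agree to one pixel, and pixel-counted disk areas at ≤ 20 µm agree
  with closed forms to well under 1%, so nothing is gained below 10 µm.
* **Exact ties** in a map are broken by the first pixel in row-major order,
  with a warning — relevant only for degenerate (e.g. constant) maps.
* **"No response" floor.** A component must exceed `floor_k` times the SD
  of its best channel's pre-stimulus baseline. Because the search
  maximizes over ~60 channels × ~140 samples, the expected maximum of
  baseline-level noise is itself ≈ 3.8 SD; a 3-SD floor would fire on
  noise alone, so the default is `floor_k = 5` (false-detection
  probability ≈ 0.002 under the study conditions, while genuine components
  sit tens of SDs above baseline). Absence of a component is a legal
  outcome, not an error, matching pre-hearing-onset and post-ablation
  recordings.

### Calibrating footprints through the reference

One design subtlety deserves emphasis. Common-average referencing
subtracts, at each time point, the across-channel mean of the field. For a
Gaussian footprint of unit peak this turns the measured map into
$g(\mathbf{x}) - \bar m$, where $\bar m$ is the mean gain over the 60
electrodes, so the *measured* half-maximum region is
$\{g \ge (1 + \bar m)/2\}$ with radius
$\sigma \sqrt{2 \ln\!\frac{2}{1 + \bar m}}$ — smaller than the
unreferenced $\sigma\sqrt{2\ln 2}$. With the default N footprint,
$\bar m \approx 0.2$, a ~20% area effect. Generator defaults are therefore
calibrated by solving the reference-aware relation
(`sigma_for_halfwidth_area()`, `referenced_halfwidth_radius()`) so the
designed areas and overlap fractions are what the *full pipeline*
measures; the unreferenced closed form
$\sigma = \sqrt{A / (2\pi\ln 2)}$ remains available
(`referenced = FALSE`). Overlap-scenario radii are designed from the
circle-lens closed form (`lens_area()`), which the pixel-counting
measurement reproduces to < 1%.

A related sampling limit: a 400 µm grid can localize the peak of a smooth
footprint to map-pixel accuracy only when the footprint is adequately
sampled ($\sigma \gtrsim$ pitch). For sharper fields the spline's argmax
is biased toward the nearest electrode by up to ~30 µm — an information
limit, not an implementation artifact (a thin-plate-spline interpolant
fares worse). The cross-modality scenario therefore mirrors the BC
footprint scales by default rather than shrinking the P footprint below
the pitch.

## Statistics

* **Rayleigh test** of circular uniformity: $\bar R$, $Z = n\bar R^2$, with
  the standard second-order series p-value, clipped to (0, 1]. Validated in
  the test suite against a 10⁵-draw Monte-Carlo null at n = 23; the p-value
  is rotation-invariant.
* **Circular mean ± SEM** from the circular dispersion
  $\hat\delta = (1 - \hat\rho_2) / (2\hat\rho_1^2)$,
  $\text{SEM} = \sqrt{\hat\delta / n}$. Coincident peaks ($r = 0$) have no
  angle and are excluded upstream.
* **Spearman correlation** (mid-ranks, two-sided) and the **one-sided
  Wilcoxon rank-sum test** (exact by enumeration when n ≤ 20 without ties,
  else normal approximation with tie/continuity correction) delegate to
  the standard R implementations behind the package interface; the test
  suite holds the exact branch to full enumeration over all rank
  assignments.
* **Exponential developmental trend**
  $a e^{-b(\text{age}-\text{age}_0)} + c$: the decay rate $b \ge 0$ is
  profiled — for fixed $b$ the problem is linear in $(a, c)$ — and the
  profiled RSS is minimized over a 61-point multi-start grid refined by
  golden-section search. Flat data collapse to $b = 0$ with $a + c$ equal
  to the sample mean. Group summaries are mean ± SEM; all p-values are
  reported raw at a nominal 0.05 level, with no multiple-testing
  correction, mirroring the original analysis style.

## Laminar analysis

Multiunit activity is the 0.25–4 kHz zero-phase band-pass; spikes are
troughs below −4.5 robust SDs (median absolute deviation) with a 1 ms
refractory period — deliberately a threshold detector, not a spike sorter,
since the analysis needs multiunit rates only. PSTHs use 5 ms half-open
bins. The LFP branch mirrors the surface chain (low-pass, 2 kHz,
epoch, average), and the current source density is the second spatial
difference $-(\phi_{i-1} - 2\phi_i + \phi_{i+1})/h^2$ over interior sites
with unit conductivity (arbitrary units): sinks negative, depth-constant
(volume-conducted) signals cancel exactly, linear depth profiles map to
zero. No edge padding is applied — the two edge sites are simply dropped,
because any padding rule would manufacture data at the probe ends.

## Problem sizes used in the shipped checks

Noise-free recovery runs use 3-trial sessions at 4 kHz (noise-free
averages are trial-count-invariant); noisy structural and detection-floor
checks use 6–8 trials; the laminar recovery uses 4–6 trials at 20 kHz.
These sizes were chosen as the smallest at which each check is
informative, keeping the full suite fast while the generator's *default*
conditions (44 trials) remain those of the study protocol.

## Known limitations

* Isotropic footprints only; the optional anisotropy of real N components
  is not modelled, so caudolateral *spread* (as opposed to displacement) is
  not reproduced.
* The half-maximum region of a component whose footprint leaks outside the
  hull is truncated; the flag is reported but no extrapolation is
  attempted.
* Peak localization accuracy degrades below footprint σ ≈ electrode pitch
  (see above).
* The spike detector does not resolve overlapping spikes closer than the
  refractory period; collision losses at high evoked rates bias PSTHs
  slightly downward.
* CSD output units are arbitrary (unit conductivity); only spatiotemporal
  structure, not absolute current density, is interpretable.
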