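Package: sepmap
Title: Topographic Mapping and Statistics for Sensory-Evoked Cortical Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multichannel sensory-evoked potentials
    recorded with epidural micro-electrocorticography (uECoG) grids and
    laminar silicon probes. Provides a synthetic-session generator with
    known ground truth (biphasic P/N evoked components with Gaussian or
    disk spatial footprints, laminar sink/source dipoles and evoked
    spiking), preprocessing (stimulus-onset detection, anti-aliased
    downsampling, epoching, bad-channel replacement, common-average
    referencing, baseline correction, trial averaging), component-peak
    detection with sub-sample latency refinement, spline-interpolated
    amplitude maps, half-maximum area and overlap quantification, polar
    peak displacements, circular statistics (Rayleigh test of uniformity,
    circular mean and SEM), rank-based group statistics, exponential
    developmental-trend fitting, and depth-resolved analysis (multiunit
    threshold detection, peristimulus time histograms, current source
    density). Includes a raw-binary + JSON container format and an
    end-to-end pipeline driver producing reproducible report tables.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
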