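Package: figseg
Title: Motion-Defined Figure-Ground Stimuli and TMS-EEG Difference-Wave Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying figure-ground segregation with concurrent
    transcranial magnetic stimulation (TMS) and EEG. Generates balanced
    random-dot stack/frame/homogenous motion stimuli and randomized trial
    schedules; simulates multichannel TMS-EEG recordings and behavioral
    tables with known ground truth; implements a TMS-artifact-aware
    preprocessing chain (artifact excision with cubic-spline interpolation,
    ringing-free mirror filtering, downsampling, re-referencing, regression
    ocular correction, threshold artifact rejection, spherical-spline
    surface Laplacian, epoching, baseline correction, peri-occipital
    pooling); and provides the difference-wave statistics used to isolate
    figure-border detection and surface segregation (sample-wise paired
    t-tests with Benjamini-Hochberg FDR control, cumulative window
    statistics, within-subject repeated-measures ANOVA and error-type
    analyses of behavior).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
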