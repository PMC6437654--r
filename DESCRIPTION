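Package: slantchoice
Title: Stimulus and Choice Signals in Spiking Activity During Fine Slant Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-neuron spiking data recorded while an
    observer discriminates the slant of a 3D planar surface. Quantifies
    slant-tilt tuning (surface orientation discrimination index, one-way ANOVA,
    Bingham-function fits, equal-area preference maps), fits psychometric and
    ROC-based neurometric cumulative Gaussians, computes choice probabilities
    (including the balanced z-scored grand choice probability with a
    permutation null), dissociates stimulus from choice signals with partial
    correlations and confidence-ellipse summaries, and tracks all of these in
    sliding time windows. A synthetic-session generator with a noisy-observer
    behavioral model and controllable neuron-choice coupling provides
    ground-truth data for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
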