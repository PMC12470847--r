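Package: prfadapt
Title: Population Receptive Field Mapping Under Spatial Frequency Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis of population receptive field (pRF)
    mapping experiments in which the bar mapping stimulus is embedded in
    spatial frequency (SF) adaptation. Provides the visual-field aperture
    generator for a bar-sweep mapping run, a neural-subpopulation simulator
    in which receptive field size is inversely linked to preferred SF and
    adapter-tuned gain suppression reshapes the aggregate pRF, a 2D Gaussian
    pRF estimator with coarse-to-fine (grid then Nelder-Mead) fitting of the
    correlation between predicted and observed BOLD time series, split-half
    reliability and Spearman-Brown noise-ceiling quality control, Mood's
    median tests with sliding eccentricity binning and repeated-measures
    ANOVA for the group analysis, and an interleaved one-up one-down
    staircase arm with log-normal psychometric fitting for the perceptual
    SF aftereffect.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
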