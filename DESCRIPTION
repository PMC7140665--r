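Package: epifish
Title: Statistical Integration of LFP and Two-Photon Calcium Imaging for
    Epileptiform Activity in Larval Zebrafish
Version: 0.1.0
Authors@R:
    person("epifish", "authors", email = "epifish@example.org",
           role = c("aut", "cre"))
Description: Unbiased detection and quantification of epileptiform activity
    from paired local field potential (LFP) recordings and time-lapse
    two-photon calcium imaging of larval zebrafish. Provides band-limited
    sliding RMS power of the LFP and its decomposition into a Gaussian Main
    Mode and a high-power Secondary Mode by iterative tail trimming;
    per-pixel deltaF/F0, Pearson skewness maps and statistical binarization
    of imaging stacks; spatiotemporal (x, y, t) connected-component
    clustering of calcium domains with anatomical classification; pixelwise
    cross-correlation maps localizing the sources of LFP transients;
    single-neuron detection, PCA and classification of epileptiform versus
    pre-epileptiform neuronal cohorts; a frame-wise motion metric; and a
    fully deterministic synthetic-data generator producing paired
    LFP/imaging recordings with ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
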