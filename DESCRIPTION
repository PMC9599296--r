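Package: docmflow
Title: Directed Information Flow and Dominant Coupling Modes for Electrophysiological Source Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the direction, strength and time delay of effective
    (causal) coupling between regional electrophysiological time series, within
    and between six canonical frequency bands and separately for amplitude and
    phase dynamics. Amplitude-domain flow is quantified with delay symbolic
    transfer entropy on Neural-Gas vector-quantized embeddings; phase-domain
    flow with histogram-based phase transfer entropy. Three-level surrogate
    statistics (permutation or epoch-shuffle nulls, Bonferroni selection across
    the 21 candidate coupling modes, network-level false-discovery-rate control)
    identify one dominant coupling mode per region pair and epoch, summarised as
    comodulograms. Lifespan summaries include a posterior-anterior index, age
    grouped time delays, and a frequency-dependent brain age index with
    two-segment Gaussian curve fits. Graph-diffusion-distance and
    delay-stability criteria filter unstable epochs, and a synthetic cohort
    generator with planted, ground-truth couplings supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
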