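Package: odorint
Title: Odor Plume Intermittency: Stimulus Quantification, Sniff-Gated
    Perception, and Olfactory Bulb Encoding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how animals and olfactory bulb glomeruli
    encode the intermittency of turbulent odor plumes. Quantifies stimulus
    intermittency (the fraction of time odor concentration exceeds 10% of the
    source concentration), whiff counts and gain scaling; detects sniffs from
    nasal pressure traces and computes the intermittency of the odor actually
    inhaled; preprocesses wide-field calcium imaging traces (dF/F, zero-phase
    Butterworth band filtering, polynomial bleach correction, exponential-kernel
    deconvolution, baseline z-scoring); computes glomerular intermittency (GI),
    GI-vs-intermittency slopes, encoding ANOVAs and shuffle-corrected stimulus
    cross-correlations; clusters glomeruli by their GI tuning profiles and
    decodes trial identity with cross-validated linear discriminants; and scores
    Go/No-Go behavior (hit and false-alarm rates, engagement trimming,
    first-lick latencies). Includes a synthetic-session generator with known
    ground truth (plume-like renewal-process stimuli, sniff waveforms, two
    planted glomerular response phenotypes, and a lick policy) so that every
    stage of the pipeline has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
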