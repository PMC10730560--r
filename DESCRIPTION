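Package: phonobench
Title: Aero-Acoustic and Mechanical Analysis of Vocal-Fold Replica Phonation Benches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-reduction and modeling chain for in vitro phonation
    experiments with deformable vocal-fold replicas. Implements a
    quasi-steady Bernoulli glottal-flow model with the Liljencrants
    flow-separation criterion (forward, inverse and iso-resistance
    abacuses), reduction of raw airflow/pressure/audio time series to
    per-step aero-acoustic descriptors (fundamental frequency by the YIN
    method, sound pressure level, harmonic-to-noise ratio, glottal flow
    resistance), high-speed-video glottal-area segmentation and
    videokymography, phenomenological pressure-flow and SPL fits, and
    post-processing of cyclic mechanical tests (tangent moduli, adhesion
    traces). A synthetic bench generator emulates every input with known
    ground truth so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    pracma,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
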