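Package: audiphen
Title: Auditory Phenotyping of Mouse Models: USV Detection, Cortical Tuning,
    Ensemble Decoding, Behavioral Sensitivity, and ABR Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An auditory-phenotyping analysis pipeline for mouse models of
    developmental hearing disorders. Detects neonatal ultrasonic vocalization
    (USV) syllables in high-bandwidth audio by spectrogram band-energy
    thresholding and extracts per-call spectral and temporal features;
    estimates cortical frequency-response areas (FRA) from tone-evoked
    calcium-imaging trials and scores tuning quality with a resampled d-prime
    statistic; decodes tone frequency from ensemble activity with a
    cross-validated linear support-vector machine summarized by octave
    separation; scores go/no-go lick behavior into signal-detection d-prime;
    and estimates auditory-brainstem-response (ABR) thresholds and wave-I
    amplitudes. A synthetic-data module generates every input with known
    ground truth so the full chain is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    car,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
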