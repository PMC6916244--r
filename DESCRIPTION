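Package: xylemAE
Title: Acoustic Emission Detection of Drought-Induced Xylem Embolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking ultrasonic acoustic emissions (AE) to
    drought-induced xylem embolism observed by X-ray microtomography (microCT).
    Provides microCT time-series image differencing with local-maxima event
    detection, a count-weighted linear discriminant analysis that learns
    per-signal embolism posteriors from window-level microCT event counts
    (weak supervision), parameter-wise and model ROC screening, and
    construction and comparison of acoustic and microCT vulnerability curves,
    including the third-derivative endpoint rule, native-embolism rescaling
    and a segmented stress-strain mapping from dendrometer strain to xylem
    water potential. A synthetic experiment generator with known ground truth
    makes the whole pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
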