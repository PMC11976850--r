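Package: ms1prop
Title: MS1-Centric Peptide Identity Propagation by Scan-Wise Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Transfers peptide identifications between liquid
    chromatography ion-mobility mass spectrometry runs using MS1
    evidence only. Precursor dictionaries with isotope envelopes and
    retention-time/ion-mobility search windows are built from search
    engine evidence tables; every MS1 frame is deconvoluted against its
    scan-specific dictionary by non-negative least squares, yielding
    per-precursor activation images over retention time and inverse
    reduced ion mobility; a trainable peak-selection segmentation model
    and a confidence scorer filter the images; and identifications are
    reported under target-decoy false discovery rate control with
    sequence-mutation decoys. Ships a synthetic-data generator that
    emulates multi-species mixture designs so the whole pipeline is
    testable without raw vendor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
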