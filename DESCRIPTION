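Package: clamplock
Title: Quantitative Pipelines for an RNA Polymerase Clamp-Locking Repressor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipelines for characterising a viral protein that binds
    the archaeal RNA polymerase DNA-binding channel and locks the clamp:
    tight-binding (Morrison) dissociation-constant estimation from EMSA
    titrations, crosslinking mass-spectrometry distance validation of residue
    pairs against a structure with a random-pair null distribution and
    interface outlier calling, single-molecule FRET histogram analysis with
    one- and two-Gaussian least-squares fits, model-order selection and
    Forster efficiency-to-distance conversion, and leaderless-promoter TATA
    motif scanning with transcription-unit prediction.  Every pipeline is
    paired with a synthetic-data generator with recorded ground truth, so the
    whole workflow runs and is testable without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    bio3d,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
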