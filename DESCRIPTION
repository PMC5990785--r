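Package: hoovar
Title: Context-Specific Acoustic Variation in Chimpanzee Hoo Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing context-specific variants of quiet
    chimpanzee "hoo" calls. Implements the full analysis chain for
    repeated-measures bioacoustic classification: acoustic feature
    measurement from fundamental-frequency contours and framewise spectra,
    variable transformation and collinearity screening (pairwise
    correlation and variance inflation factors), a crossed permuted
    discriminant function analysis (pDFA) with balanced training-call
    selection and a within-subject label-permutation null, Gaussian linear
    mixed models with likelihood-ratio tests of context effects, and a
    synthetic call-bout generator with known ground truth for calibration
    and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
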