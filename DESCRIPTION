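Package: pneaselect
Title: Active Selection of Non-Experimentally Annotated Proteins for
    Multi-Label Subcellular Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mines proteins whose subcellular-location annotations carry
    non-experimental evidence qualifiers ("Probable", "Potential",
    "By similarity") as supplementary training data for multi-label
    subcellular localization classifiers.  Each candidate's worst-case
    classification risk is evaluated with a weighted, kernel regularized
    least-squares model; candidates are ranked in ascending order of risk,
    and a preferred proportion of the pool is selected automatically from
    the stabilization of the evaluation-value change rates.  Includes
    amphiphilic pseudo amino acid composition features, Parzen-window
    posterior confidence for non-experimental labels, generic multi-label
    baseline classifiers, the six standard multi-label evaluation metrics,
    a synthetic-study generator, and a repeated cross-validation harness
    comparing training with none, the preferred proportion, or all of the
    candidate pool.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
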