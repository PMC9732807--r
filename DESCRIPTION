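Package: snirfio
Title: Read, Write and Validate Shared Near-Infrared Spectroscopy Format (SNIRF) Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-memory data model, HDF5 reader and writer, and rule-based
    compliance validator for the Shared Near-Infrared Spectroscopy Format
    (SNIRF), the community standard container for functional near-infrared
    spectroscopy (fNIRS) recordings. Implements the indexed-group naming
    convention, measurement-list cross-reference resolution from data channels
    to probe geometry, severity-graded machine-readable validation reports,
    a synthetic continuous-wave fixture generator with a single-defect
    corruptor for exercising every validation rule, and a command-line
    interface for validation, inspection, example creation and tabular export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    rhdf5,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
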