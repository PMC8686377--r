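Package: cbpstudio
Title: Programmatic Creation, Editing and Validation of cBioPortal Study Directories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, reads, edits, merges and validates cBioPortal study
    directories from code instead of a point-and-click interface. Covers the
    six cBioPortal data types used in Molecular Tumor Board documentation
    (cancer study metadata, patient and sample clinical tables, MAF mutation
    data, patient timelines, and resources), converts calendar dates to
    cBioPortal's day-offset timeline coordinates via a first-diagnosis-date
    registry, ships a searchable OncoTree cancer-type vocabulary snapshot,
    and natively re-implements the upload-readiness validation checks with a
    downloadable error/warning report. A deterministic example-study
    generator and a command-line interface support testing and scripted ETL.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
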