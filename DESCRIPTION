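Package: contacteval
Title: Assessment and Comparison of Predicted Protein Residue-Residue Contacts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates predicted protein residue-residue contacts (CASP RR
    format) against a native structure using precision, coverage, mean
    false-positive error, the distance-distribution score Xd, contact-map
    spread, Matthews correlation, and ROC / precision-recall curves; compares
    multiple prediction sets without a native structure via Jaccard similarity
    with neighborhood relaxation, coordination-number profiles, contact maps
    and chord diagrams; and exports UCSF Chimera command scripts that display
    selected contacts on the structure. Includes a synthetic-data generator
    (compact, helical and extended chains plus predictions with planted
    precision) so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
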