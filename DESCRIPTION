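Package: phenopatch
Title: Marker-Gated Cell Phenotyping and Patch Classification for Multiplexed Immunofluorescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for inter-modality nucleus and cell
    subclassification in colon tissue. Simulates multiplexed
    immunofluorescence (MxIF) tissue with known per-instance phenotypes,
    derives 14-class labels from an ordered marker-gating rule cascade,
    renders a deterministic pseudo-H&E image, builds centered-patch
    classification datasets with patient-level cross-validation folds and
    class-balanced batches, trains a compact patch classifier, and evaluates
    predictions with lenient IoU instance matching, per-class PPV/NPV and
    prevalence, parent-class bounded metrics, prevalence-normalized PPV,
    per-class detection quality (DQ+), and a cross-site Friedman test.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
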