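Package: wormdecode
Title: Population Decoding of C. elegans Locomotion from Whole-Brain Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for decoding locomotion (velocity and body
    curvature) from two-channel whole-brain calcium imaging of freely moving
    C. elegans. Provides ratiometric motion correction of GCaMP fluorescence
    against an RFP reference channel, photobleach correction and outlier
    handling, extraction of velocity and mean body curvature from worm
    centerlines, circular-shift permutation tests of single-neuron tuning
    with Bonferroni control, ridge-regression population decoders with
    temporal-derivative features (plus acceleration-penalty and elastic-net
    variants), best-single-neuron and truncated-model (N90) analyses, and
    correlation-structure comparison between moving and immobilized epochs
    (dissimilarity statistic, epoch-fit PCA state space, reference-neuron
    correlation shifts). Includes a seeded synthetic-data generator with
    known ground truth for validation of the full pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    minpack.lm,
    glmnet,
    MASS,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
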