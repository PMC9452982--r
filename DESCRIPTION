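Package: MIRFusion
Title: Mutual-Information Registration and Fusion of PET/CT Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Rigid registration of 2D PET slices to CT slices by
    maximizing the mutual information between the PET gray values and a
    binary CT edge image extracted with a Chua-Yang cellular neural
    network, followed by colour-overlay fusion and threshold-based
    segmentation of high-uptake regions. Includes joint-histogram
    entropy and mutual-information estimators, a deterministic grid plus
    coordinate-descent optimizer, a synthetic CT/PET phantom generator
    with ground-truth transforms and lesion masks for benchmarking, and
    a RECIST response-tally utility for short-term efficacy summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, RNifti, png, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
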