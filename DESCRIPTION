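Package: bundlerepro
Title: Reproducibility Assessment of Manual White-Matter Bundle Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify agreement between raters who manually segment
    white-matter bundles from diffusion MRI tractograms. Bundles are handled in
    two representations: as sets of streamline indices into a shared parent
    tractogram and as voxel-grid density maps or binary masks. The package reads
    and writes TRK/TCK tractograms and NIfTI maps, computes pairwise overlap and
    agreement measures (Dice, Jaccard, density-map correlation, confusion-based
    classification metrics including Cohen's kappa and the Youden index), builds
    vote-based average segmentations across raters, and provides a blinded
    triplication study harness (flip/translate duplication, anonymization,
    de-randomization, triplicate fusion, intra-/inter-rater and gold-standard
    scoring with median/IQR summaries and Mann-Whitney group comparison). A
    synthetic phantom and rater simulator with controllable reliability makes
    the whole pipeline testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    RNifti,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
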