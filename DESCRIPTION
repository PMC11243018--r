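Package: svmscreen
Title: SVM-Assisted Metabolomics Screening of Pesticide and Veterinary Drug Residues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-targeted screening of multi-class pesticide and veterinary
    drug residues from LC-MS feature tables. Implements internal-standard
    recovery calibration and RSD filtering, PCA and hierarchical-clustering
    diagnostics, OPLS-DA with VIP scores, S-plots and permutation-test
    validation, SMOTE class balancing, RBF-kernel SVM model selection and
    SVM-RFE weight-squared variable ranking, consensus candidate selection
    with pairwise t-tests and fold changes, accurate-mass ppm matching
    against a compound library, and EPA-style method detection limits.
    Includes a synthetic-data generator that emulates a spiked-maize
    three-concentration study design so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    stats,
    utils,
    yaml
Suggests:
    withr,
    jsonlite,
    optparse,
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
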