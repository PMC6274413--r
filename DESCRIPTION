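Package: wavePPBS
Title: Sequence-Based Prediction of Protein-Protein Binding-Site Residues
    from Wavelet Physicochemical Features
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies protein-protein binding-site (interface) residues from
    sequence alone. Each residue is represented by a 15-residue mirror-extended
    sliding window, encoded under seven standardized amino-acid physicochemical
    scales (hydrophobicity, hydrophilicity, side-chain volume, polarity,
    polarizability, solvent-accessible surface area, net charge index),
    decomposed with a four-level stationary Haar wavelet transform, and
    summarized by per-sub-band max/mean/min/SD statistics into a 7 x 20 feature
    block. Highly imbalanced training sets are optimized by K-nearest-neighbour
    cleaning of the negative subset and SMOTE-style insertion of hypothetical
    minority samples to exact balance. Seven per-property random-forest
    classifiers are fused by majority voting into an ensemble predictor.
    Includes surface/interface residue labeling from accessible-surface-area
    tables, the target 10-fold cross-validation protocol that scores only
    experiment-confirmed residues, a K-scan for the cleaning parameter, and a
    seeded synthetic benchmark generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    FNN,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Proteomics, Classification, FeatureExtraction, MachineLearning
RoxygenNote: 7.3.3
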