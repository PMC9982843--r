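Package: connGradients
Title: Functional Connectome Gradient Analysis with Clinical and Transcriptomic Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds cortical functional-hierarchy gradients from regional
    rs-fMRI time series (Pearson connectome, Fisher z, row-wise top-fraction
    thresholding, cosine affinity, PCA embedding), aligns per-subject
    embeddings to a group template by Procrustes rotation, and compares
    groups through ROI-wise and seed-based gradient-distance statistics with
    Benjamini-Hochberg FDR control. Includes tinnitus instruments (THI
    scoring and severity levels, VAS), Fisher-exact cohort contingency
    analysis, leave-one-out stepwise regression for symptom prediction with
    a selection-reliability criterion, and imaging-transcriptomics via PLS
    regression with permutation significance and running-sum gene-set
    enrichment. A synthetic-cohort generator with planted gradient effects,
    clinical coupling and signal genes makes every stage testable without
    access to raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), vegan, mixOmics, fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
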