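Package: lmrsecretome
Title: Low-Molecular-Mass Secretome Biomarker Discovery for Oral Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis workflow for discovering low-molecular-mass (LMr,
    < 15 kDa) candidate biomarkers from cancer cell-line secretomes.
    Implements decoy-database false-positive-rate estimation for
    peptide-spectrum matches, probability- and peptide-count-based
    identification filtering, theoretical protein mass computation and
    true-LMr classification, secretion-route triage from signal-peptide,
    non-classical-secretion and transmembrane-helix predictor scores,
    tumor-versus-normal microarray meta-analysis (pooled t-tests, T/N
    ratio ranking, top-fraction selection), cross-omics candidate
    integration, and the clinical verification statistics used to assess
    candidates (immunohistochemistry H-scores, Wilcoxon tests,
    Kaplan-Meier / log-rank survival analysis and Cox proportional-hazards
    regression). A synthetic-data module generates every pipeline input
    with known ground truth so the full workflow is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    survival,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
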